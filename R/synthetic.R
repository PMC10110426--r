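# Synthetic-data generators: trigger trains, scalp recordings with embedded
# phase-locked responses, band-limited artifact waveforms, and parcel signals
# with known directed coupling. Everything is deterministic under `seed` and
# leaves the caller's RNG state untouched.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a jittered stimulus trigger train
#'
#' Inter-stimulus intervals are `1/rate` plus independent Gaussian jitter, so
#' the sample mean/SD of the intervals reproduce the stimulator's reported
#' ISI statistics. The first trigger is at t = 0; triggers past `duration`
#' are dropped.
#'
#' @param rate Stimulation rate in Hz (default 1.78).
#' @param duration Recording duration in seconds.
#' @param isi_jitter_sd SD of the ISI jitter in milliseconds (default 2.9).
#' @param seed Integer seed.
#' @return Numeric vector of trigger times in seconds.
#' @export
generate_trigger_train <- function(rate = 1.78, duration, isi_jitter_sd = 2.9,
                                   seed = 1) {
  if (rate <= 0 || duration <= 0) {
    ckc_stop("rate and duration must be positive", "invalid_parameter")
  }
  if (isi_jitter_sd < 0) ckc_stop("isi_jitter_sd must be >= 0", "invalid_parameter")
  n_max <- ceiling(duration * rate) + 10L
  isi <- rep(1 / rate, n_max)
  if (isi_jitter_sd > 0) {
    isi <- isi + with_seed(seed, stats::rnorm(n_max, 0, isi_jitter_sd / 1000))
  }
  t <- c(0, cumsum(isi))
  t[t < duration]
}

# 1/f ("pink") background noise, channels x samples, exact per-channel RMS.
# A shared common-mode term (mixing 0.3) gives the channels spatial
# correlation for the CSD transform to remove.
pink_noise <- function(n_channels, n_samples, fs, rms, common_mixing = 0.3) {
  shape_one <- function() {
    z <- stats::rnorm(n_samples)
    X <- stats::fft(z)
    f <- seq(0, fs, length.out = n_samples + 1)[1:n_samples]
    f <- pmin(f, fs - f)
    amp <- ifelse(f > 0, 1 / sqrt(f), 0)
    Re(stats::fft(X * amp, inverse = TRUE)) / n_samples
  }
  common <- shape_one()
  out <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    x <- shape_one() + common_mixing * common
    out[ch, ] <- x / sqrt(mean(x^2)) * rms
  }
  out
}

#' Generate a synthetic scalp EEG recording with an embedded phase-locked response
#'
#' Produces a 10--20 scalp recording of 1/f background noise plus, on the
#' selected response channels, a sinusoid at `response_freq` that is re-phased
#' at every stimulation trigger with a wrapped-Gaussian phase offset
#' (SD `phase_jitter_sd`). This emulates the steady-state component that
#' repetitive movement stimulation evokes at the first harmonic of the
#' stimulation rate.
#'
#' @param duration Seconds.
#' @param fs Sampling rate, Hz.
#' @param channel_labels Channel montage labels (default: 21-channel 10--20).
#' @param stim_rate Trigger rate, Hz.
#' @param isi_jitter_sd ISI jitter SD, milliseconds.
#' @param response_freq Response frequency, Hz (first harmonic of `stim_rate`).
#' @param response_channels Named numeric vector of per-channel response gains
#'   in `[0, 1]`, e.g. `c(C3 = 1, C4 = 1)`. Names must be montage channels.
#' @param response_amplitude Peak amplitude in microvolts, or `NULL` to make
#'   the response RMS equal the realized background RMS within
#'   `response_freq` +/- 0.5 Hz (in-band SNR of 1).
#' @param phase_jitter_sd Wrapped-Gaussian SD (radians) of the per-trigger
#'   response phase. 0 gives perfect phase locking.
#' @param noise_amplitude Background 1/f noise RMS, microvolts.
#' @param spike_fraction Fraction of triggers contaminated by a large
#'   transient spike (for artifact-rejection testing); contaminated trigger
#'   indices are recorded in the `contaminated_triggers` attribute.
#' @param spike_amplitude Spike peak amplitude, microvolts.
#' @param seed Integer seed.
#' @return An `eeg_recording` with triggers attached.
#' @export
generate_scalp_recording <- function(duration,
                                     fs = 250,
                                     channel_labels = montage_1020()$label,
                                     stim_rate = 1.78,
                                     isi_jitter_sd = 2.9,
                                     response_freq = 3.56,
                                     response_channels = c(C3 = 1, C4 = 1),
                                     response_amplitude = NULL,
                                     phase_jitter_sd = 1.0,
                                     noise_amplitude = 20,
                                     spike_fraction = 0,
                                     spike_amplitude = 500,
                                     seed = 1) {
  if (fs <= 2 * response_freq) ckc_stop("fs must exceed 2 x response_freq", "invalid_parameter")
  if (duration <= 0) ckc_stop("duration must be positive", "invalid_parameter")
  if (phase_jitter_sd < 0) ckc_stop("phase_jitter_sd must be >= 0", "invalid_parameter")
  unknown <- setdiff(names(response_channels), channel_labels)
  if (length(unknown) > 0) {
    ckc_stop(paste0("unknown response channel(s): ", paste(unknown, collapse = ", ")),
             "unknown_channel")
  }

  n <- round(duration * fs)
  triggers <- generate_trigger_train(stim_rate, duration, isi_jitter_sd, seed = seed + 1L)

  with_seed(seed, {
    signals <- if (noise_amplitude > 0) {
      pink_noise(length(channel_labels), n, fs, noise_amplitude)
    } else {
      matrix(0, length(channel_labels), n)
    }

    if (is.null(response_amplitude)) {
      if (noise_amplitude <= 0) {
        ckc_stop("response_amplitude = NULL needs non-zero background noise",
                 "invalid_parameter")
      }
      bg <- eeg_recording(signals, fs, channel_labels)
      # peak = sqrt(2) x band RMS, so the sinusoid's RMS matches the
      # background RMS in the response band (in-band SNR 1)
      response_amplitude <- sqrt(2) *
        mean(band_rms(bg, c(response_freq - 0.5, response_freq + 0.5))$rms)
    }

    if (response_amplitude > 0 && length(response_channels) > 0 && length(triggers) > 0) {
      t_axis <- (seq_len(n) - 1) / fs
      phases <- stats::rnorm(length(triggers), 0, phase_jitter_sd)
      # segment index: which trigger governs each sample (last trigger runs out)
      seg <- findInterval(t_axis, triggers)
      resp <- numeric(n)
      active <- seg >= 1
      resp[active] <- sin(2 * pi * response_freq * (t_axis[active] - triggers[seg[active]]) +
                            phases[seg[active]])
      for (ch in names(response_channels)) {
        i <- match(ch, channel_labels)
        signals[i, ] <- signals[i, ] + response_amplitude * response_channels[[ch]] * resp
      }
    }

    contaminated <- integer(0)
    if (spike_fraction > 0 && length(triggers) > 0) {
      n_bad <- round(spike_fraction * length(triggers))
      contaminated <- sort(sample.int(length(triggers), n_bad))
      width <- max(3L, round(0.02 * fs))
      shape <- spike_amplitude * exp(-((seq_len(width) - width / 2)^2) / (width / 6)^2)
      for (k in contaminated) {
        i0 <- round((triggers[k] + 0.3) * fs)
        idx <- i0 + seq_len(width)
        idx <- idx[idx >= 1 & idx <= n]
        signals[, idx] <- sweep(signals[, idx, drop = FALSE], 2,
                                shape[seq_along(idx)], "+")
      }
    }

    rec <- eeg_recording(signals, fs, channel_labels, triggers)
    attr(rec, "contaminated_triggers") <- contaminated
    attr(rec, "response_amplitude") <- response_amplitude
    rec
  })
}

#' Generate a band-limited artifact waveform
#'
#' Synthesizes one of four artifact classes with the canonical contamination
#' bands: `emg` (band-limited white noise, 5--70 Hz), `device` (mains 50 Hz
#' plus harmonics on a broadband floor, 2--125 Hz), `respiration` (slow
#' ~0.8 Hz oscillation band-limited to 1--30 Hz) and `ecg` (periodic sharp
#' biphasic spikes at ~2.4 Hz, band-limited to 2--35 Hz). Every channel is
#' normalized to unit RMS.
#'
#' @param kind One of `"emg"`, `"device"`, `"respiration"`, `"ecg"`.
#' @param n_channels Number of channels.
#' @param duration Seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @return An `artifact_template`: list with `kind`, `band` (Hz), `fs` and
#'   `waveform` (channels x samples, unit RMS).
#' @export
generate_artifact <- function(kind, n_channels, duration, fs = 250, seed = 1) {
  bands <- list(emg = c(5, 70), device = c(2, 125),
                respiration = c(1, 30), ecg = c(2, 35))
  if (!kind %in% names(bands)) {
    ckc_stop(paste0("unknown artifact kind: ", kind), "invalid_parameter")
  }
  band <- bands[[kind]]
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  raw <- with_seed(seed, {
    switch(kind,
      emg = matrix(stats::rnorm(n_channels * n), n_channels, n),
      device = {
        harmonics <- seq(50, min(fs / 2 - 5, 125), by = 50)
        m <- matrix(stats::rnorm(n_channels * n, sd = 0.3), n_channels, n)
        for (ch in seq_len(n_channels)) {
          for (h in harmonics) {
            m[ch, ] <- m[ch, ] + (1 / which(harmonics == h)) *
              sin(2 * pi * h * t + stats::runif(1, 0, 2 * pi))
          }
        }
        m
      },
      respiration = {
        m <- matrix(0, n_channels, n)
        for (ch in seq_len(n_channels)) {
          ph <- stats::runif(1, 0, 2 * pi)
          # peaky periodic bump train: fundamental 0.8 Hz with harmonics
          m[ch, ] <- exp(3 * (cos(2 * pi * 0.8 * t + ph) - 1)) +
            0.05 * stats::rnorm(n)
        }
        m
      },
      ecg = {
        period <- 1 / 2.4
        width <- round(0.03 * fs)
        shape <- diff(exp(-((seq_len(width + 1) - width / 2)^2) / (width / 5)^2))
        m <- matrix(0, n_channels, n)
        beat_times <- seq(0, duration, by = period)
        for (ch in seq_len(n_channels)) {
          x <- numeric(n)
          jit <- stats::runif(1, 0, period)
          for (bt in beat_times + jit) {
            i0 <- round(bt * fs)
            idx <- i0 + seq_along(shape)
            ok <- idx >= 1 & idx <= n
            x[idx[ok]] <- x[idx[ok]] + shape[ok]
          }
          m[ch, ] <- x + 0.02 * stats::rnorm(n)
        }
        m
      }
    )
  })

  wave <- band_limit(raw, fs, band)
  wave <- wave / sqrt(rowMeans(wave^2))
  structure(list(kind = kind, band = band, fs = fs, waveform = wave),
            class = "artifact_template")
}

# zero-phase Butterworth band limiting; degenerates to high-pass when the
# upper edge reaches Nyquist
band_limit <- function(x, fs, band, order = 5) {
  nyq <- fs / 2
  x <- as.matrix(x)
  out <- x
  if (band[1] > 0) {
    hp <- signal::butter(order, band[1] / nyq, type = "high")
    for (ch in seq_len(nrow(x))) out[ch, ] <- signal::filtfilt(hp, out[ch, ])
  }
  if (band[2] < nyq * 0.999) {
    lp <- signal::butter(order, band[2] / nyq, type = "low")
    for (ch in seq_len(nrow(x))) out[ch, ] <- signal::filtfilt(lp, out[ch, ])
  }
  out
}

#' Generate parcel signals with known directed phase coupling
#'
#' Each parcel is a stochastic phase oscillator at `carrier_freq`: its phase
#' advances at the carrier rate plus Gaussian phase noise, and the signal is
#' the cosine of the phase -- narrowband noise centred on the carrier. For
#' every coupling edge the target's phase additionally relaxes towards the
#' source's phase `lag` samples earlier (lag-compensated sine coupling with
#' gain proportional to `strength`), so phase information flows
#' source -> target with known ground truth that directed
#' phase-transfer-entropy estimation can recover.
#'
#' @param duration Seconds.
#' @param fs Sampling rate, Hz.
#' @param parcels Parcel metadata tibble (default [parcel_table()]).
#' @param carrier_freq Oscillator frequency, Hz.
#' @param phase_noise_sd Per-sample phase-noise SD, radians (default 0.05;
#'   sets the signal bandwidth around the carrier).
#' @param coupling_gain Coupling gain at `strength = 1` (default 0.5).
#' @param coupling_edges Data frame with columns `source`, `target` (parcel
#'   labels), `lag` (samples, >= 1) and `strength` in `[0, 1]`.
#' @param noise_sd Amplitude scale of the parcel signals (arbitrary units).
#' @param seed Integer seed.
#' @return A `parcel_signals` object: list with `data` (parcels x samples),
#'   `fs`, and `parcels` metadata.
#' @export
generate_parcel_signals <- function(duration,
                                    fs = 250,
                                    parcels = parcel_table(),
                                    carrier_freq = 3.56,
                                    phase_noise_sd = 0.05,
                                    coupling_gain = 0.5,
                                    coupling_edges = NULL,
                                    noise_sd = 1,
                                    seed = 1) {
  n <- round(duration * fs)
  labels <- parcels$label
  n_p <- length(labels)
  if (anyDuplicated(labels)) ckc_stop("parcel labels must be unique", "invalid_parameter")
  has_edges <- !is.null(coupling_edges) && NROW(coupling_edges) > 0
  if (has_edges) {
    if (any(coupling_edges$source == coupling_edges$target)) {
      ckc_stop("self-loop coupling edges are not allowed", "invalid_parameter")
    }
    if (any(coupling_edges$lag < 1)) ckc_stop("lags must be >= 1 sample", "invalid_parameter")
    if (any(coupling_edges$strength < 0 | coupling_edges$strength > 1)) {
      ckc_stop("strengths must be in [0, 1]", "invalid_parameter")
    }
    bad <- setdiff(c(coupling_edges$source, coupling_edges$target), labels)
    if (length(bad) > 0) {
      ckc_stop(paste0("unknown parcel(s): ", paste(bad, collapse = ", ")),
               "invalid_parameter")
    }
  }

  omega <- 2 * pi * carrier_freq / fs
  data <- with_seed(seed, {
    noise <- matrix(stats::rnorm(n_p * n, 0, phase_noise_sd), n_p, n)
    theta <- matrix(0, n_p, n)
    theta[, 1] <- stats::runif(n_p, -pi, pi)
    if (!has_edges) {
      theta <- t(apply(cbind(theta[, 1], noise[, -1, drop = FALSE] + omega),
                       1, cumsum))
    } else {
      src_i <- match(coupling_edges$source, labels)
      tgt_i <- match(coupling_edges$target, labels)
      lag_i <- as.integer(coupling_edges$lag)
      gain <- coupling_gain * coupling_edges$strength
      for (t in 2:n) {
        drift <- rep(omega, n_p)
        for (e in seq_along(src_i)) {
          if (t - 1 - lag_i[e] >= 1) {
            # relax towards the source phase lag samples ago, lag-compensated
            drift[tgt_i[e]] <- drift[tgt_i[e]] + gain[e] *
              sin(theta[src_i[e], t - 1 - lag_i[e]] + lag_i[e] * omega -
                    theta[tgt_i[e], t - 1])
          }
        }
        theta[, t] <- theta[, t - 1] + drift + noise[, t]
      }
    }
    noise_sd * cos(theta)
  })

  structure(list(data = data, fs = fs, parcels = parcels),
            class = "parcel_signals")
}

#' @export
print.parcel_signals <- function(x, ...) {
  cat(sprintf("<parcel_signals> %d parcels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
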