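# Preprocessing: zero-phase Butterworth band limiting, spectral resampling,
# greedy non-overlapping trigger-locked epoching with per-epoch mean detrend,
# and amplitude-threshold epoch rejection.

#' Band-pass filter and resample a recording
#'
#' Applies separate high-pass and low-pass Butterworth filters of the given
#' order, each forward and reverse (zero phase), then resamples exactly in
#' the spectral domain (the band limit makes Fourier resampling alias-free).
#' Trigger times are kept in seconds and are unaffected by resampling.
#'
#' @param recording An `eeg_recording`.
#' @param low,high Band edges in Hz (defaults 0.5 and 30).
#' @param order Butterworth order per pass (default 5).
#' @param target_fs Output sampling rate, Hz (default 250).
#' @return A filtered, resampled `eeg_recording`.
#' @export
filter_and_resample <- function(recording, low = 0.5, high = 30, order = 5,
                                target_fs = 250) {
  fs <- recording$fs
  if (fs < 2 * high) ckc_stop("sampling rate below 2 x high cutoff (aliasing)", "aliasing_error")
  if (low >= high) ckc_stop("low must be below high", "invalid_parameter")
  nyq <- fs / 2
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  x <- recording$signals
  out <- t(apply(x, 1, function(ch) {
    signal::filtfilt(lp, signal::filtfilt(hp, ch))
  }))
  if (!isTRUE(all.equal(target_fs, fs))) {
    if (target_fs < 2 * high) ckc_stop("target_fs below 2 x high cutoff", "aliasing_error")
    n_out <- round(ncol(out) * target_fs / fs)
    out <- t(apply(out, 1, fft_resample, n_out = n_out))
  }
  eeg_recording(out, target_fs, recording$channel_labels, recording$trigger_times)
}

# exact spectral resampling of an (anti-alias filtered) signal: truncate or
# zero-pad the spectrum so both grids start at t = 0
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  half <- floor(min(n, n_out) / 2)
  Y <- complex(length.out = n_out)
  Y[1] <- X[1]
  Y[1 + seq_len(half)] <- X[1 + seq_len(half)]
  Y[n_out + 1 - seq_len(half - 1)] <- X[n + 1 - seq_len(half - 1)]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Segment a recording into trigger-locked, non-overlapping epochs
#'
#' Scans triggers in time order and greedily accepts a trigger if its epoch
#' window (`pre` ms before to `post` ms after the trigger) lies fully inside
#' the recording and does not overlap the previously accepted epoch. Each
#' epoch is detrended by subtracting its per-channel mean.
#'
#' @param recording An `eeg_recording` with trigger times.
#' @param pre Milliseconds before the trigger (default 200).
#' @param post Milliseconds after the trigger (default 900).
#' @return An `eeg_epochs` object: `data` (epochs x channels x samples),
#'   `fs`, `time_ms` (relative to trigger), `channel_labels`,
#'   `kept_trigger_indices`, `rejection_log` tibble and a `units` field.
#' @export
epoch_recording <- function(recording, pre = 200, post = 900) {
  fs <- recording$fs
  trig <- recording$trigger_times
  if (length(trig) == 0) ckc_stop("recording has no triggers", "empty_epochs")
  n_samp <- round((pre + post) / 1000 * fs)
  duration <- rec_duration(recording)

  kept <- integer(0)
  last_end <- -Inf
  starts <- numeric(0)
  n_total <- ncol(recording$signals)
  for (k in seq_along(trig)) {
    t0 <- trig[k] - pre / 1000
    t1 <- trig[k] + post / 1000
    if (t0 >= 0 && t1 <= duration && round(t0 * fs) + n_samp <= n_total &&
        t0 >= last_end) {
      kept <- c(kept, k)
      starts <- c(starts, t0)
      last_end <- t1
    }
  }
  if (length(kept) == 0) ckc_stop("no admissible trigger for epoching", "empty_epochs")

  n_ch <- nrow(recording$signals)
  data <- array(0, dim = c(length(kept), n_ch, n_samp))
  for (e in seq_along(kept)) {
    i0 <- round(starts[e] * fs)
    seg <- recording$signals[, i0 + seq_len(n_samp), drop = FALSE]
    data[e, , ] <- seg - rowMeans(seg)
  }
  time_ms <- (seq_len(n_samp) - 1) / fs * 1000 - pre

  structure(
    list(data = data, fs = fs, time_ms = time_ms,
         channel_labels = recording$channel_labels,
         kept_trigger_indices = kept,
         trigger_times = trig[kept],
         rejection_log = tibble::tibble(epoch = integer(0), reason = character(0)),
         units = "uV"),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz [%s]\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs, x$units))
  invisible(x)
}

n_epochs <- function(epochs) dim(epochs$data)[1]

#' Reject epochs by amplitude threshold
#'
#' Drops any epoch whose absolute value exceeds `amplitude_threshold` on any
#' channel. The dropped epochs and overall dropped fraction are recorded in
#' the `rejection_log`.
#'
#' @param epochs An `eeg_epochs`.
#' @param amplitude_threshold Peak absolute amplitude threshold (same units
#'   as the epochs; default 250).
#' @return The pruned `eeg_epochs`.
#' @export
reject_epochs <- function(epochs, amplitude_threshold = 250) {
  if (amplitude_threshold <= 0) ckc_stop("threshold must be positive", "invalid_parameter")
  peak <- apply(abs(epochs$data), 1, max)
  drop <- which(peak > amplitude_threshold)
  if (length(drop) == n_epochs(epochs)) {
    ckc_stop("all epochs exceed the amplitude threshold", "empty_epochs")
  }
  if (length(drop) > 0) {
    epochs$data <- epochs$data[-drop, , , drop = FALSE]
    epochs$trigger_times <- epochs$trigger_times[-drop]
    epochs$rejection_log <- dplyr::bind_rows(
      epochs$rejection_log,
      tibble::tibble(epoch = epochs$kept_trigger_indices[drop],
                     reason = sprintf("amplitude > %g", amplitude_threshold))
    )
    epochs$kept_trigger_indices <- epochs$kept_trigger_indices[-drop]
  }
  attr(epochs, "dropped_fraction") <- length(drop) / (length(drop) + n_epochs(epochs))
  epochs
}
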