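# The CKC metric: inter-trial phase coherence at the pinned response
# frequency, parametric Rayleigh significance, BH-FDR across channels, the
# FFT-based alternative estimator and the cumulative epoch-count sweep.

#' Inter-trial phase coherence
#'
#' `ITC = |1/N sum_n exp(i theta_n)|` over epochs, per channel, frequency and
#' time sample. Values are in `[0, 1]`; 1 means perfect phase locking across
#' trials.
#'
#' @param phases A `tfr_phase` from [wavelet_phase()], or a numeric array
#'   whose first dimension is epochs.
#' @return Numeric array (channels x frequencies x time for a `tfr_phase`
#'   input; one dimension fewer than the input otherwise).
#' @export
itc <- function(phases) {
  ph <- if (inherits(phases, "tfr_phase")) phases$phase else phases
  ph <- as.array(ph)
  n <- dim(ph)[1]
  if (n < 2) ckc_stop("ITC needs at least 2 epochs", "insufficient_trials")
  re <- colMeans(cos(ph), dims = 1)
  im <- colMeans(sin(ph), dims = 1)
  sqrt(re^2 + im^2)
}

#' Rayleigh-test P value for an ITC value
#'
#' Closed-form approximation of the circular-uniformity (Rayleigh) test
#' P value for a mean resultant length `itc_value` over `N` trials:
#' `P = exp(sqrt(1 + 4N + 4N^2 (1 - ITC^2)) - (1 + 2N))`, clipped to
#' `(1e-300, 1]`. Valid for reasonably large `N`.
#'
#' @param itc_value ITC value(s) in `[0, 1]`.
#' @param n Number of trials (>= 2).
#' @return P value(s), same shape as `itc_value`.
#' @export
rayleigh_p <- function(itc_value, n) {
  if (any(n < 2)) ckc_stop("Rayleigh approximation needs N >= 2", "insufficient_trials")
  p <- exp(sqrt(1 + 4 * n + 4 * n^2 * (1 - itc_value^2)) - (1 + 2 * n))
  pmin(pmax(p, 1e-300), 1)
}

#' CKC metric with Rayleigh significance and FDR across channels
#'
#' Per channel, CKC is the mean ITC at the response-frequency bin over the
#' epoch interior (the first and last `edge_exclusion` ms excluded, i.e.
#' 0--700 ms post-trigger for the default 1100 ms epochs), and the aggregated
#' P value is the mean of the per-sample Rayleigh P values over the same
#' window. A channel is detected when its aggregated P is below `alpha`;
#' Benjamini--Hochberg FDR across channels at `fdr_q` sets the final
#' significance flags.
#'
#' @param phases A `tfr_phase` containing the response-frequency bin.
#' @param n Number of epochs the phases came from.
#' @param response_freq Response frequency, Hz (default 3.56).
#' @param edge_exclusion Milliseconds excluded from each epoch edge (200).
#' @param alpha Detection threshold on the aggregated P (default 0.01).
#' @param fdr_q BH-FDR level across channels (default 0.01).
#' @param keep_itc_map Keep the full ITC array for plotting (default FALSE).
#' @return A `ckc_result`: per-channel tibble (`channel`, `ckc`, `p`,
#'   `p_adj`, `significant`) plus `n_epochs`, `response_freq`.
#' @export
ckc_metric <- function(phases, n = dim(phases$phase)[1], response_freq = 3.56,
                       edge_exclusion = 200, alpha = 0.01, fdr_q = 0.01,
                       keep_itc_map = FALSE) {
  fi <- which(abs(phases$frequencies - response_freq) < 1e-9)
  if (length(fi) != 1) {
    ckc_stop("response frequency is not a bin of the phase decomposition",
             "invalid_parameter")
  }
  itc_map <- itc(phases)                     # channels x freqs x time
  tmin <- min(phases$time_ms) + edge_exclusion
  tmax <- max(phases$time_ms) - edge_exclusion
  win <- phases$time_ms >= tmin & phases$time_ms <= tmax

  itc_win <- itc_map[, fi, win, drop = FALSE]
  ckc <- apply(itc_win, 1, mean)
  p <- apply(rayleigh_p(itc_win, n), 1, mean)
  p_adj <- stats::p.adjust(p, method = "BH")
  channels <- tibble::tibble(
    channel = phases$channel_labels,
    ckc = as.numeric(ckc),
    p = as.numeric(p),
    p_adj = p_adj,
    significant = p < alpha & p_adj <= fdr_q
  )
  structure(
    list(channels = channels, n_epochs = n, response_freq = response_freq,
         alpha = alpha, fdr_q = fdr_q, method = "wavelet",
         itc_map = if (keep_itc_map) itc_map else NULL,
         frequencies = phases$frequencies, time_ms = phases$time_ms),
    class = "ckc_result"
  )
}

#' @export
print.ckc_result <- function(x, ...) {
  peak <- x$channels[which.max(x$channels$ckc), ]
  cat(sprintf("<ckc_result> %s method, %d epochs @ %.3g Hz: peak CKC %.3f (%s), %d/%d significant\n",
              x$method, x$n_epochs, x$response_freq, peak$ckc, peak$channel,
              sum(x$channels$significant), nrow(x$channels)))
  invisible(x)
}

#' @method tidy ckc_result
#' @export
tidy.ckc_result <- function(x, ...) x$channels

#' @method glance ckc_result
#' @export
glance.ckc_result <- function(x, ...) {
  peak <- which.max(x$channels$ckc)
  tibble::tibble(
    method = x$method, n_epochs = x$n_epochs,
    response_freq = x$response_freq,
    peak_ckc = x$channels$ckc[peak],
    peak_channel = x$channels$channel[peak],
    n_significant = sum(x$channels$significant),
    any_significant = any(x$channels$significant)
  )
}

#' FFT-based CKC (spectral phase coherence)
#'
#' Alternative estimator: per epoch and channel, the discrete-Fourier phase
#' at the bin nearest the response frequency (epochs zero-padded until the
#' bin spacing is at most `max_bin_spacing` Hz), ITC across epochs, and the
#' same Rayleigh / FDR machinery as the wavelet path.
#'
#' @param epochs An `eeg_epochs`.
#' @inheritParams ckc_metric
#' @param max_bin_spacing Maximum FFT bin spacing, Hz (default 0.25).
#' @return A `ckc_result` with `method = "fft"`.
#' @export
ckc_fft <- function(epochs, response_freq = 3.56, alpha = 0.01, fdr_q = 0.01,
                    max_bin_spacing = 0.25) {
  d <- epochs$data
  n_ep <- dim(d)[1]; n_ch <- dim(d)[2]; n_s <- dim(d)[3]
  if (n_ep < 2) ckc_stop("need at least 2 epochs", "insufficient_trials")
  nfft <- 2^ceiling(log2(epochs$fs / max_bin_spacing))
  nfft <- max(nfft, n_s)
  bin <- which.min(abs((0:(nfft - 1)) * epochs$fs / nfft - response_freq))

  sig <- matrix(aperm(d, c(3, 1, 2)), nrow = n_s)
  S <- stats::mvfft(rbind(sig, matrix(0, nfft - n_s, ncol(sig))))
  phs <- matrix(Arg(S[bin, ]), nrow = n_ep)   # epochs x channels

  z <- exp(1i * phs)
  itc_ch <- Mod(colMeans(z))
  p <- rayleigh_p(itc_ch, n_ep)
  p_adj <- stats::p.adjust(p, method = "BH")
  channels <- tibble::tibble(
    channel = epochs$channel_labels,
    ckc = itc_ch, p = p, p_adj = p_adj,
    significant = p < alpha & p_adj <= fdr_q
  )
  structure(
    list(channels = channels, n_epochs = n_ep, response_freq = response_freq,
         alpha = alpha, fdr_q = fdr_q, method = "fft",
         itc_map = NULL, frequencies = response_freq, time_ms = epochs$time_ms),
    class = "ckc_result"
  )
}

#' Detection performance as a function of epoch count
#'
#' Re-evaluates CKC detection on cumulative epoch prefixes (the first
#' `step`, `2*step`, ... epochs), applying the Rayleigh/FDR machinery within
#' each prefix. Phases are computed once; prefix ITCs come from cumulative
#' phasor sums.
#'
#' @param epochs An `eeg_epochs` (typically CSD-transformed).
#' @param bank A `wavelet_bank`; defaults to the standard bank at the epoch
#'   sampling rate.
#' @param step Prefix increment in epochs (default 10).
#' @inheritParams ckc_metric
#' @return A tibble with columns `n_epochs`, `peak_ckc`, `peak_channel`,
#'   `n_significant`, `any_significant`.
#' @export
epoch_count_sweep <- function(epochs, bank = build_wavelet_bank(epochs$fs),
                              step = 10, response_freq = 3.56,
                              edge_exclusion = 200, alpha = 0.01, fdr_q = 0.01) {
  n_tot <- n_epochs(epochs)
  if (n_tot < step) ckc_stop("fewer epochs than one sweep step", "invalid_parameter")
  phases <- wavelet_phase(epochs, bank, frequencies = "pinned")
  ph <- phases$phase[, , 1, , drop = TRUE]     # epochs x channels x time
  dim(ph) <- c(n_tot, dim(phases$phase)[2], dim(phases$phase)[4])
  win <- phases$time_ms >= min(phases$time_ms) + edge_exclusion &
         phases$time_ms <= max(phases$time_ms) - edge_exclusion
  ph <- ph[, , win, drop = FALSE]

  cre <- apply(cos(ph), c(2, 3), cumsum)
  cim <- apply(sin(ph), c(2, 3), cumsum)

  purrr::map_dfr(seq(step, n_tot, by = step), function(n) {
    itc_n <- sqrt(cre[n, , ]^2 + cim[n, , ]^2) / n
    ckc <- rowMeans(itc_n)
    p <- rowMeans(rayleigh_p(itc_n, n))
    p_adj <- stats::p.adjust(p, method = "BH")
    sig <- p < alpha & p_adj <= fdr_q
    peak <- which.max(ckc)
    tibble::tibble(n_epochs = n, peak_ckc = ckc[peak],
                   peak_channel = phases$channel_labels[peak],
                   n_significant = sum(sig), any_significant = any(sig))
  })
}
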