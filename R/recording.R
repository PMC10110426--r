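#' Construct an EEG recording container
#'
#' @param signals Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `signals`.
#' @param trigger_times Numeric vector of stimulus trigger times in seconds.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, fs, channel_labels, trigger_times = numeric(0)) {
  signals <- as.matrix(signals)
  stopifnot(is.numeric(signals), fs > 0)
  if (nrow(signals) != length(channel_labels)) {
    ckc_stop("channel_labels length must match nrow(signals)", "invalid_parameter")
  }
  if (anyDuplicated(channel_labels)) {
    ckc_stop("channel labels must be unique", "invalid_parameter")
  }
  duration <- ncol(signals) / fs
  if (length(trigger_times) > 0 &&
      (min(trigger_times) < 0 || max(trigger_times) > duration)) {
    ckc_stop("trigger times must lie within [0, duration]", "invalid_parameter")
  }
  structure(
    list(signals = signals, fs = fs,
         channel_labels = as.character(channel_labels),
         trigger_times = as.numeric(trigger_times)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d triggers\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs, length(x$trigger_times)))
  invisible(x)
}

rec_duration <- function(recording) ncol(recording$signals) / recording$fs

#' RMS of a recording within a frequency band
#'
#' Band-limits each channel with an FFT brick-wall mask and returns the
#' per-channel root-mean-square amplitude. Used e.g. to express response
#' amplitudes relative to the background level in the response band.
#'
#' @param recording An `eeg_recording`.
#' @param band Length-2 numeric, Hz.
#' @return A tibble with columns `channel`, `rms`.
#' @export
band_rms <- function(recording, band) {
  x <- recording$signals
  n <- ncol(x)
  freqs <- seq(0, recording$fs, length.out = n + 1)[1:n]
  freqs <- pmin(freqs, recording$fs - freqs)  # two-sided
  keep <- freqs >= band[1] & freqs <= band[2]
  rms <- apply(x, 1, function(ch) {
    X <- stats::fft(ch)
    X[!keep] <- 0
    sqrt(mean(Re(stats::fft(X, inverse = TRUE) / n)^2))
  })
  tibble::tibble(channel = recording$channel_labels, rms = rms)
}

#' Write / read a recording in the plain-text internal container
#'
#' Signals are stored as a CSV (one column per channel) alongside a JSON
#' sidecar (`<path>.json`) holding sampling rate, channel labels and trigger
#' times.
#'
#' @param recording An `eeg_recording`.
#' @param path Path of the CSV file to write / read.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(recording, path) {
  df <- as.data.frame(t(recording$signals))
  names(df) <- recording$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = recording$fs,
               channel_labels = recording$channel_labels,
               trigger_times = recording$trigger_times)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  eeg_recording(t(as.matrix(df)), fs = meta$fs,
                channel_labels = meta$channel_labels,
                trigger_times = as.numeric(meta$trigger_times))
}
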