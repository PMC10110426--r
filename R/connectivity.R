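# Directed phase transfer entropy between parcel signals.
# Phases come from a tight forward-backward FIR band constraint around the
# response frequency followed by the analytic-signal (Hilbert) phase; PTE is
# estimated from binned phase occurrence histograms (natural log), with the
# Scott rule for the bin count and a phase-sign-change heuristic for the
# prediction delay; the two directions are normalized to dPTE.

#' Project scalp channels to cortical parcels with a linear operator
#'
#' Stands in for a user-supplied source projection: each sample of the
#' channel data is multiplied by `projection` (parcels x channels).
#'
#' @param x An `eeg_recording` or a channels x samples matrix.
#' @param projection Numeric matrix, parcels x channels.
#' @param parcels Parcel metadata tibble with one row per projection row.
#' @return A `parcel_signals` object.
#' @export
project_to_parcels <- function(x, projection, parcels = parcel_table()) {
  sig <- if (inherits(x, "eeg_recording")) x$signals else as.matrix(x)
  fs <- if (inherits(x, "eeg_recording")) x$fs else
    ckc_stop("matrix input needs an eeg_recording for its sampling rate",
             "invalid_parameter")
  if (ncol(projection) != nrow(sig) || nrow(projection) != nrow(parcels)) {
    ckc_stop("projection shape does not match channels/parcels", "invalid_operator")
  }
  structure(list(data = projection %*% sig, fs = fs, parcels = parcels),
            class = "parcel_signals")
}

# zero-phase FIR filtering via FFT convolution: equivalent to forward plus
# reverse application of `b` (convolution with b * rev(b), zero-padded,
# "same" alignment), which is what signal::filtfilt does for an FIR filter
fir_filtfilt_fft <- function(b, x) {
  b <- as.numeric(b)
  k <- convolve(b, b, type = "open")   # b conv rev(b): symmetric, zero phase
  n <- length(x); L <- length(k)
  nfft <- stats::nextn(n + L - 1, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  K <- stats::fft(c(k, rep(0, nfft - L)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  y[(L - 1) / 2 + seq_len(n)]
}

# analytic signal phase via FFT (Hilbert transform)
analytic_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(X * h, inverse = TRUE) / n)
}

#' Narrowband instantaneous phase of parcel signals
#'
#' Constrains each parcel signal tightly around the response frequency with
#' separate high-pass and low-pass Hamming-window FIR filters (each applied
#' forward and backward), then extracts the analytic-signal phase. The first
#' and last `fir_order` samples are discarded to remove filter edge effects.
#'
#' @param parcels A `parcel_signals`, or a numeric matrix (series x samples)
#'   with `fs` supplied.
#' @param center Band centre, Hz (default 3.56).
#' @param halfwidth Band half-width, Hz (default 0.3).
#' @param fir_order FIR filter order (default 626).
#' @param fs Sampling rate if `parcels` is a bare matrix.
#' @return Numeric matrix of phases (series x samples), radians.
#' @export
narrowband_phase <- function(parcels, center = 3.56, halfwidth = 0.3,
                             fir_order = 626, fs = NULL) {
  x <- if (inherits(parcels, "parcel_signals")) parcels$data else as.matrix(parcels)
  if (inherits(parcels, "parcel_signals")) fs <- parcels$fs
  if (is.null(fs)) ckc_stop("fs required for matrix input", "invalid_parameter")
  if (ncol(x) <= 3 * fir_order) {
    ckc_stop("signal too short for the FIR band constraint", "length_error")
  }
  nyq <- fs / 2
  hp <- signal::fir1(fir_order, (center - halfwidth) / nyq, type = "high")
  lp <- signal::fir1(fir_order, (center + halfwidth) / nyq, type = "low")
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    f <- fir_filtfilt_fft(lp, fir_filtfilt_fft(hp, x[i, ]))
    if (stats::sd(f) < 1e-14) {
      ckc_stop("degenerate (near-constant) signal after band constraint",
               "degenerate_signal")
    }
    out[i, ] <- analytic_phase(f)
  }
  keep <- (fir_order + 1):(ncol(x) - fir_order)
  out[, keep, drop = FALSE]
}

entropy_nats <- function(idx, n_levels) {
  counts <- if (n_levels > 4096) {
    # scanning a mostly empty 3-D histogram is slower than sorting the sample
    rle(sort.int(idx, method = "radix"))$lengths
  } else {
    cnt <- tabulate(idx, n_levels)
    cnt[cnt > 0L]
  }
  n <- sum(counts)
  log(n) - sum(counts * log(counts)) / n
}

bin_phases <- function(ph, n_bins) {
  b <- floor((ph + pi) / (2 * pi) * n_bins) + 1L
  pmin.int(pmax.int(b, 1L), n_bins)
}

#' Scott-rule bin count for phase histograms
#'
#' Bin width `3.49 * sd(x) * n^(-1/3)` over the pooled phase sample, turned
#' into a bin count over the `2 pi` phase range.
#'
#' @param phases Numeric vector/matrix of phases.
#' @return Integer bin count (>= 2).
#' @export
scott_bins <- function(phases) {
  w <- 3.49 * stats::sd(phases) * length(phases)^(-1 / 3)
  max(2L, as.integer(ceiling(2 * pi / w)))
}

# prediction-delay heuristic: samples x series / total phase sign changes
auto_delay <- function(phase_mat) {
  changes <- sum(apply(phase_mat, 1, function(p) sum(diff(sign(p)) != 0)))
  if (changes == 0) return(1L)
  max(1L, as.integer(round(length(phase_mat) / changes)))
}

#' Phase transfer entropy between two phase series
#'
#' `PTE_xy = H(y_t, y_{t-d}) + H(y_{t-d}, x_{t-d}) - H(y_{t-d}) -
#' H(y_t, y_{t-d}, x_{t-d})`, entropies in nats from joint occurrence
#' histograms with `n_bins` bins per axis and prediction delay `d` samples.
#'
#' @param phase_x,phase_y Equal-length numeric phase series, radians.
#' @param delay Prediction delay in samples (`"auto"` for the sign-change
#'   heuristic).
#' @param n_bins Bins per histogram axis (`"scott"` for the Scott rule on the
#'   pooled sample).
#' @return Named numeric vector `c(pte_xy = ..., pte_yx = ...)`.
#' @export
pte_pair <- function(phase_x, phase_y, delay = "auto", n_bins = "scott") {
  if (length(phase_x) != length(phase_y)) {
    ckc_stop("phase series must have equal length", "invalid_parameter")
  }
  if (stats::sd(phase_x) < 1e-14 || stats::sd(phase_y) < 1e-14) {
    ckc_stop("constant phase series", "degenerate_signal")
  }
  pm <- rbind(phase_x, phase_y)
  d <- if (identical(delay, "auto")) auto_delay(pm) else as.integer(delay)
  if (length(phase_x) <= 10 * d) {
    ckc_stop("phase series too short for the requested delay", "invalid_parameter")
  }
  B <- if (identical(n_bins, "scott")) scott_bins(pm) else as.integer(n_bins)
  bx <- bin_phases(phase_x, B)
  by <- bin_phases(phase_y, B)
  c(pte_xy = pte_core(bx, by, d, B), pte_yx = pte_core(by, bx, d, B))
}

# PTE from x to y given binned series
pte_core <- function(bx, by, delay, B) {
  T <- length(bx)
  fut <- (1 + delay):T
  past <- 1:(T - delay)
  y_fut <- by[fut]; y_past <- by[past]; x_past <- bx[past]
  H_ypast <- entropy_nats(y_past, B)
  H_yy <- entropy_nats(y_fut + B * (y_past - 1L), B^2)
  H_yx <- entropy_nats(y_past + B * (x_past - 1L), B^2)
  H_yyx <- entropy_nats(y_fut + B * (y_past - 1L) + B^2 * (x_past - 1L), B^3)
  H_yy + H_yx - H_ypast - H_yyx
}

#' All-valid fidelity mask
#'
#' @param n Number of parcels (default 58).
#' @return Logical n x n matrix, `TRUE` off the diagonal.
#' @export
fidelity_mask_full <- function(n = 58) {
  m <- matrix(TRUE, n, n)
  diag(m) <- FALSE
  m
}

#' Read a fidelity mask from a 0/1 CSV
#'
#' The mask is symmetrized (an edge is valid only if marked in both
#' directions) and the diagonal forced invalid.
#'
#' @param path CSV file of 0/1 values, no header.
#' @return Logical matrix.
#' @export
read_fidelity_mask <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  m <- (m != 0) & (t(m) != 0)
  diag(m) <- FALSE
  unname(m)
}

#' Directed phase-transfer-entropy interaction matrix
#'
#' Computes PTE for every valid ordered parcel pair and normalizes the two
#' directions to `dPTE_xy = PTE_xy / (PTE_xy + PTE_yx)`, so
#' `dPTE_xy + dPTE_yx = 1` and 0.5 means no preferred direction. Masked and
#' degenerate (zero total PTE) edges are `NA` and excluded from every
#' downstream summary.
#'
#' @param parcels A `parcel_signals` object, or a ready phase matrix
#'   (parcels x samples) with `phases_ready = TRUE`.
#' @param mask Logical validity matrix (default: all valid, diagonal FALSE).
#' @param delay `"auto"` or samples.
#' @param n_bins `"scott"` or a fixed bin count.
#' @param center,halfwidth,fir_order Narrowband filter settings passed to
#'   [narrowband_phase()].
#' @param parcel_meta Parcel metadata when `parcels` is a bare phase matrix.
#' @param phases_ready Set `TRUE` when `parcels` already contains phases.
#' @return An `interaction_matrix`: list with `dpte`, `pte`, `mask`,
#'   `parcels`, `band`, `delay`, `n_bins`.
#' @export
dpte_matrix <- function(parcels, mask = NULL, delay = "auto", n_bins = "scott",
                        center = 3.56, halfwidth = 0.3, fir_order = 626,
                        parcel_meta = NULL, phases_ready = FALSE) {
  if (phases_ready) {
    ph <- as.matrix(parcels)
    meta <- parcel_meta
  } else {
    ph <- narrowband_phase(parcels, center = center, halfwidth = halfwidth,
                           fir_order = fir_order)
    meta <- parcels$parcels
  }
  n <- nrow(ph)
  if (is.null(meta)) {
    meta <- tibble::tibble(label = paste0("P", seq_len(n)),
                           hemisphere = NA_character_, lobe = NA_character_)
  }
  if (n < 2) ckc_stop("need at least 2 parcels", "invalid_parameter")
  if (is.null(mask)) mask <- fidelity_mask_full(n)
  if (!all(dim(mask) == c(n, n))) ckc_stop("mask shape mismatch", "incompatible_inputs")
  mask <- mask & t(mask)
  diag(mask) <- FALSE

  d <- if (identical(delay, "auto")) auto_delay(ph) else as.integer(delay)
  B <- if (identical(n_bins, "scott")) scott_bins(ph) else as.integer(n_bins)

  T <- ncol(ph)
  if (T <= 10 * d) ckc_stop("phase series too short for the delay", "invalid_parameter")
  binned <- t(apply(ph, 1, bin_phases, n_bins = B))
  fut <- (1 + d):T
  past <- 1:(T - d)

  # per-parcel terms reused across pairs
  H_past <- numeric(n)
  H_self <- numeric(n)
  for (i in seq_len(n)) {
    H_past[i] <- entropy_nats(binned[i, past], B)
    H_self[i] <- entropy_nats(binned[i, fut] + B * (binned[i, past] - 1L), B^2)
  }

  pte <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!mask[i, j]) next
      xi <- binned[i, past]; xj <- binned[j, past]
      H_cross <- entropy_nats(xi + B * (xj - 1L), B^2)
      # x = i, y = j
      H3_ij <- entropy_nats(binned[j, fut] + B * (xj - 1L) + B^2 * (xi - 1L), B^3)
      pte[i, j] <- H_self[j] + H_cross - H_past[j] - H3_ij
      # x = j, y = i
      H3_ji <- entropy_nats(binned[i, fut] + B * (xi - 1L) + B^2 * (xj - 1L), B^3)
      pte[j, i] <- H_self[i] + H_cross - H_past[i] - H3_ji
    }
  }

  dpte <- matrix(NA_real_, n, n)
  tot <- pte + t(pte)
  ok <- mask & !is.na(tot) & tot > 0
  dpte[ok] <- pte[ok] / tot[ok]
  # estimator noise can push a tiny PTE slightly negative; clamp the pair so
  # dpte stays in [0,1] while dpte_xy + dpte_yx = 1 still holds exactly
  dpte[ok] <- pmin(pmax(dpte[ok], 0), 1)
  undefined <- mask & (!ok | is.na(tot))

  dimnames(dpte) <- dimnames(pte) <- list(meta$label, meta$label)
  structure(
    list(dpte = dpte, pte = pte, mask = mask, parcels = meta,
         band = c(center - halfwidth, center + halfwidth),
         delay = d, n_bins = B,
         n_undefined = sum(undefined & upper.tri(undefined))),
    class = "interaction_matrix"
  )
}

#' @export
print.interaction_matrix <- function(x, ...) {
  v <- x$dpte[x$mask & !is.na(x$dpte)]
  cat(sprintf("<interaction_matrix> %d parcels, band %.2f-%.2f Hz, delay %d, %d bins; mean dPTE %.3f\n",
              nrow(x$dpte), x$band[1], x$band[2], x$delay, x$n_bins, mean(v)))
  invisible(x)
}

#' @method tidy interaction_matrix
#' @export
tidy.interaction_matrix <- function(x, ...) {
  idx <- which(x$mask & !is.na(x$dpte), arr.ind = TRUE)
  tibble::tibble(
    source = x$parcels$label[idx[, 1]],
    target = x$parcels$label[idx[, 2]],
    dpte = x$dpte[idx],
    pte = x$pte[idx]
  )
}

#' Write / read an interaction matrix's dPTE values as labelled CSV
#'
#' @param x An `interaction_matrix`.
#' @param path CSV path.
#' @return `write_interaction_matrix` returns `path` invisibly;
#'   `read_interaction_matrix` returns a labelled numeric matrix.
#' @export
write_interaction_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x$dpte), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
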