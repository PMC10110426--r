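# Current source density via spherical-spline surface Laplacian.
# The spline interpolates the scalp potential over a sphere with Legendre
# series kernels; applying the (sign-flipped) surface Laplacian to the spline
# and scaling by 1/head_radius^2 yields CSD in uV/m^2. For a fixed montage
# and configuration the whole transform is one reusable n x n matrix.

legendre_poly <- function(x, n_max) {
  # rows: order 1..n_max, columns: x
  out <- matrix(0, n_max, length(x))
  p_prev <- rep(1, length(x))  # P0
  p_cur <- x                   # P1
  out[1, ] <- p_cur
  if (n_max >= 2) {
    for (n in 1:(n_max - 1)) {
      p_next <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
      out[n + 1, ] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

spline_kernels <- function(cosang, m, n_terms) {
  n <- 1:n_terms
  P <- legendre_poly(cosang, n_terms)
  gw <- (2 * n + 1) / (n * (n + 1))^m / (4 * pi)
  hw <- (2 * n + 1) / (n * (n + 1))^(m - 1) / (4 * pi)
  list(g = colSums(P * gw), h = colSums(P * hw))
}

#' Precompute the CSD transform matrix for a montage
#'
#' @param montage Tibble with columns `label`, `x`, `y`, `z` (unit-sphere
#'   positions), e.g. from [montage_1020()].
#' @param m Spline flexibility (integer >= 2, default 3).
#' @param lambda Smoothing parameter (>= 0, default 0; the spline system must
#'   be well conditioned at 0 or an error suggests `lambda > 0`).
#' @param n_legendre Number of Legendre series terms (default 50).
#' @param head_radius Sphere radius in meters (default 0.092); output units
#'   are uV/m^2 for uV input.
#' @return An n x n matrix mapping channel potentials to CSD values, with the
#'   montage labels as dimnames.
#' @export
csd_operator <- function(montage, m = 3, lambda = 0, n_legendre = 50,
                         head_radius = 0.092) {
  if (m < 2) ckc_stop("spline flexibility m must be >= 2", "invalid_parameter")
  if (lambda < 0) ckc_stop("lambda must be >= 0", "invalid_parameter")
  if (n_legendre < 20) ckc_stop("need >= 20 Legendre terms", "invalid_parameter")
  n <- nrow(montage)
  if (n < 8) ckc_stop("CSD needs at least 8 channels", "montage_error")
  pos <- as.matrix(montage[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  cosang <- pmin(1, pmax(-1, tcrossprod(pos)))

  kern <- spline_kernels(as.vector(cosang), m, n_legendre)
  G <- matrix(kern$g, n, n)
  H <- matrix(kern$h, n, n)

  A <- rbind(cbind(G + diag(lambda, n), rep(1, n)),
             c(rep(1, n), 0))
  if (rcond(A) < 1e-12) {
    ckc_stop("spline system is numerically singular; consider lambda > 0",
             "numerical_error")
  }
  Ainv <- solve(A)
  Lmat <- H %*% Ainv[1:n, 1:n, drop = FALSE] / head_radius^2
  dimnames(Lmat) <- list(montage$label, montage$label)
  Lmat
}

#' Transform epochs to current source density
#'
#' Reference-free surface-Laplacian transform of every epoch using the
#' spherical-spline operator from [csd_operator()]. Adding a common offset
#' time series to all channels leaves the output unchanged.
#'
#' @param epochs An `eeg_epochs` in microvolts.
#' @param montage Montage tibble covering every epoch channel (default the
#'   standard 10--20 montage).
#' @inheritParams csd_operator
#' @return The transformed `eeg_epochs` with `units = "uV/m^2"`.
#' @export
csd <- function(epochs, montage = montage_1020(epochs$channel_labels),
                m = 3, lambda = 0, n_legendre = 50, head_radius = 0.092) {
  missing <- setdiff(epochs$channel_labels, montage$label)
  if (length(missing) > 0) {
    ckc_stop(paste0("no montage position for: ", paste(missing, collapse = ", ")),
             "montage_error")
  }
  montage <- montage[match(epochs$channel_labels, montage$label), ]
  Lmat <- csd_operator(montage, m = m, lambda = lambda,
                       n_legendre = n_legendre, head_radius = head_radius)
  d <- epochs$data
  for (e in seq_len(dim(d)[1])) {
    d[e, , ] <- Lmat %*% d[e, , ]
  }
  epochs$data <- d
  epochs$units <- "uV/m^2"
  epochs
}
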