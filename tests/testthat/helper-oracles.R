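# Independent oracle implementations used to cross-check the package paths.
# These deliberately share no code with the implementations they verify.

# --- brute-force phase transfer entropy over explicit joint count tables ---
oracle_pte <- function(phase_x, phase_y, delay, n_bins) {
  bin <- function(p) {
    b <- as.integer(cut(p, breaks = seq(-pi, pi, length.out = n_bins + 1),
                        include.lowest = TRUE))
    b
  }
  bx <- bin(phase_x); by <- bin(phase_y)
  n <- length(bx)
  fut <- by[(1 + delay):n]
  ypa <- by[1:(n - delay)]
  xpa <- bx[1:(n - delay)]
  ent <- function(df) {
    counts <- as.numeric(table(do.call(paste, c(as.list(df), sep = "_"))))
    p <- counts / sum(counts)
    -sum(p * log(p))
  }
  pte_dir <- function(fut, ypa, xpa) {
    ent(data.frame(fut, ypa)) + ent(data.frame(ypa, xpa)) -
      ent(data.frame(ypa)) - ent(data.frame(fut, ypa, xpa))
  }
  fut_x <- bx[(1 + delay):n]
  c(pte_xy = pte_dir(fut, ypa, xpa),
    pte_yx = pte_dir(fut_x, xpa, ypa))
}

# --- spherical-spline surface Laplacian by direct per-sample dense solve ---
# Own Legendre recursion (Bonnet, upward on terms accumulated directly) and
# an explicit augmented-system solve per time sample.
oracle_csd <- function(data, montage, m = 3, lambda = 0, n_terms = 50,
                       head_radius = 0.092) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  nch <- nrow(pos)
  gh <- function(x) {
    g <- 0; h <- 0
    p_nm1 <- 1; p_n <- x
    for (n in 1:n_terms) {
      g <- g + (2 * n + 1) / (n * (n + 1))^m * p_n
      h <- h + (2 * n + 1) / (n * (n + 1))^(m - 1) * p_n
      p_np1 <- ((2 * n + 1) * x * p_n - n * p_nm1) / (n + 1)
      p_nm1 <- p_n; p_n <- p_np1
    }
    c(g / (4 * pi), h / (4 * pi))
  }
  G <- matrix(0, nch, nch); H <- matrix(0, nch, nch)
  for (i in 1:nch) for (j in 1:nch) {
    x <- min(1, max(-1, sum(pos[i, ] * pos[j, ])))
    v <- gh(x)
    G[i, j] <- v[1]; H[i, j] <- v[2]
  }
  A <- rbind(cbind(G + diag(lambda, nch), 1), c(rep(1, nch), 0))
  out <- matrix(0, nch, ncol(data))
  for (t in seq_len(ncol(data))) {
    sol <- solve(A, c(data[, t], 0))
    out[, t] <- (H %*% sol[1:nch]) / head_radius^2
  }
  out
}

# --- exact right-tail binomial probability by enumeration ---
oracle_binom_tail <- function(count, n, p) {
  if (count > n) return(0)
  sum(vapply(count:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), 0))
}

# --- construct an interaction_matrix directly from a dPTE matrix ---
make_im <- function(dpte, parcels = NULL, pte = NULL) {
  n <- nrow(dpte)
  if (is.null(parcels)) {
    parcels <- parcel_table()[seq_len(n), ]
  }
  mask <- matrix(TRUE, n, n); diag(mask) <- FALSE
  dpte[!mask] <- NA
  if (is.null(pte)) pte <- dpte
  dimnames(dpte) <- dimnames(pte) <- list(parcels$label, parcels$label)
  structure(list(dpte = dpte, pte = pte, mask = mask, parcels = parcels,
                 band = c(3.26, 3.86), delay = 1L, n_bins = 8L,
                 n_undefined = 0L),
            class = "interaction_matrix")
}

# random antisymmetric (dpte_xy + dpte_yx = 1) interaction matrix
random_im <- function(n, sd = 0.03, seed = 1, parcels = NULL) {
  set.seed(seed)
  m <- matrix(0.5, n, n)
  up <- upper.tri(m)
  m[up] <- 0.5 + rnorm(sum(up), 0, sd)
  m <- m * up + (1 - t(m)) * lower.tri(m)
  make_im(m, parcels)
}

# small epochs object built directly from an array
make_epochs <- function(data, fs = 250, pre = 200,
                        labels = paste0("ch", seq_len(dim(data)[2]))) {
  structure(
    list(data = data, fs = fs,
         time_ms = (seq_len(dim(data)[3]) - 1) / fs * 1000 - pre,
         channel_labels = labels,
         kept_trigger_indices = seq_len(dim(data)[1]),
         trigger_times = seq_len(dim(data)[1]),
         rejection_log = tibble::tibble(epoch = integer(0), reason = character(0)),
         units = "uV"),
    class = "eeg_epochs")
}

# tfr_phase object from a phase array (epochs x channels x freqs x time)
make_tfr <- function(phase, frequencies, time_ms,
                     labels = paste0("ch", seq_len(dim(phase)[2]))) {
  structure(list(phase = phase, frequencies = frequencies, fs = 250,
                 time_ms = time_ms, channel_labels = labels),
            class = "tfr_phase")
}

# edge_zscores object with planted significant edges
make_zs <- function(z, parcels, alpha = 0.01) {
  mask <- !is.na(z)
  diag(mask) <- FALSE
  z[!mask] <- NA
  sig <- !is.na(z) & stats::pnorm(z, lower.tail = FALSE) < alpha
  structure(list(z = z, significant = sig, mask = mask, alpha = alpha,
                 parcels = parcels),
            class = "edge_zscores")
}
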