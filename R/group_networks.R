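# Group-level Consistent Network: per-subject top-k binarization of the
# dPTE matrices, edge-wise right-tailed exact binomial tests against success
# probability k, and BH-FDR over the valid edges.

#' Keep the top-k fraction of directed edges of an interaction matrix
#'
#' Keeps the `ceiling(k * n_valid)` largest-dPTE directed edges. Ties are
#' broken by larger raw PTE, then by lexicographic (source, target) parcel
#' order, so the selection is deterministic.
#'
#' @param matrix An `interaction_matrix`.
#' @param k Fraction of valid directed edges to keep (0 < k <= 1).
#' @return Logical matrix of kept edges.
#' @export
top_k_binarize <- function(matrix, k = 0.05) {
  if (k <= 0 || k > 1) ckc_stop("k must be in (0, 1]", "invalid_parameter")
  valid <- matrix$mask & !is.na(matrix$dpte)
  n_valid <- sum(valid)
  if (n_valid < 1 / k) ckc_stop("too few valid edges for this k", "invalid_parameter")
  m <- ceiling(k * n_valid)
  idx <- which(valid, arr.ind = TRUE)
  ord <- order(-matrix$dpte[valid], -matrix$pte[valid],
               matrix$parcels$label[idx[, 1]], matrix$parcels$label[idx[, 2]])
  keep_idx <- idx[ord[seq_len(m)], , drop = FALSE]
  out <- base::matrix(FALSE, nrow(matrix$dpte), ncol(matrix$dpte),
                      dimnames = dimnames(matrix$dpte))
  out[keep_idx] <- TRUE
  out
}

#' Group-level Consistent Network
#'
#' Counts, per directed edge, how many subjects include the edge in their
#' individual top-`k` set, tests each count against a right-tailed exact
#' binomial null (success probability `k`, `n` subjects), and controls FDR
#' across the valid edges with Benjamini--Hochberg at `alpha`.
#'
#' @param matrices List of `interaction_matrix` objects sharing the same
#'   mask and parcel labels.
#' @param k Top-edge fraction per subject (default 0.05).
#' @param alpha Significance level (default 0.05).
#' @param fdr Apply BH FDR across valid edges (default TRUE).
#' @return A `consistent_network`: edge tibble (`source`, `target`, `count`,
#'   `p`, `p_adj`, `significant`), plus the consistency-count matrix and the
#'   test parameters.
#' @export
consistent_network <- function(matrices, k = 0.05, alpha = 0.05, fdr = TRUE) {
  n_sub <- length(matrices)
  if (n_sub < 2) ckc_stop("need at least 2 subjects", "invalid_parameter")
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(dim(m$dpte), dim(ref$dpte)) ||
        !identical(m$parcels$label, ref$parcels$label) ||
        !identical(m$mask, ref$mask)) {
      ckc_stop("interaction matrices must share mask and parcel labels",
               "incompatible_inputs")
    }
  }
  counts <- Reduce(`+`, lapply(matrices, function(m) top_k_binarize(m, k) * 1L))
  valid <- ref$mask
  idx <- which(valid, arr.ind = TRUE)
  cnt <- counts[idx]
  p <- stats::pbinom(cnt - 1, n_sub, k, lower.tail = FALSE)
  p_adj <- if (fdr) stats::p.adjust(p, method = "BH") else p
  edges <- tibble::tibble(
    source = ref$parcels$label[idx[, 1]],
    target = ref$parcels$label[idx[, 2]],
    count = as.integer(cnt),
    p = p, p_adj = p_adj,
    significant = p_adj <= alpha & cnt > 0
  )
  structure(
    list(edges = edges, counts = counts, k = k, alpha = alpha,
         n_subjects = n_sub, fdr = fdr, parcels = ref$parcels),
    class = "consistent_network"
  )
}

#' @export
print.consistent_network <- function(x, ...) {
  cat(sprintf("<consistent_network> %d subjects, k = %g, alpha = %g: %d significant edges\n",
              x$n_subjects, x$k, x$alpha, sum(x$edges$significant)))
  invisible(x)
}

#' @method tidy consistent_network
#' @export
tidy.consistent_network <- function(x, ...) x$edges

#' @method glance consistent_network
#' @export
glance.consistent_network <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, k = x$k, alpha = x$alpha,
                 n_valid_edges = nrow(x$edges),
                 n_significant = sum(x$edges$significant))
}

#' Nodal dPTE summaries
#'
#' Mean dPTE of each parcel over its valid outbound edges. Values above 0.5
#' mark net information sources, below 0.5 net sinks.
#'
#' @param matrix An `interaction_matrix`.
#' @return A tibble with `parcel`, `hemisphere`, `lobe`, `nodal_dpte`
#'   (`NA` for parcels without valid edges) and `n_edges`.
#' @export
nodal_dpte <- function(matrix) {
  valid <- matrix$mask & !is.na(matrix$dpte)
  vals <- matrix$dpte
  vals[!valid] <- NA
  tibble::tibble(
    parcel = matrix$parcels$label,
    hemisphere = matrix$parcels$hemisphere,
    lobe = matrix$parcels$lobe,
    nodal_dpte = rowMeans(vals, na.rm = TRUE),
    n_edges = rowSums(valid)
  ) |>
    dplyr::mutate(nodal_dpte = ifelse(.data$n_edges == 0, NA_real_, .data$nodal_dpte))
}
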