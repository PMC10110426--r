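# Individual-level network metrics: a control-referenced z-score matrix over
# dPTE edges, the Spreading Index (extent of significant outbound flow from
# the 4 most active source parcels of a hemisphere), and the laterality /
# symmetry ratios.

#' Reference distribution of control dPTE values
#'
#' Pools every valid dPTE entry of a control-condition interaction matrix
#' into a mean/SD reference for edge z-scoring. Control dPTEs are expected
#' to be distributed around 0.5 (no preferred direction).
#'
#' @param control An `interaction_matrix` from the control recording.
#' @return A `reference_distribution`: list with `mu`, `sigma`, `n_pooled`.
#' @export
reference_distribution <- function(control) {
  if (is.null(control)) ckc_stop("control matrix is missing; SI undefined", "missing_control")
  v <- control$dpte[control$mask & !is.na(control$dpte)]
  if (length(v) < 30) ckc_stop("too few valid control edges (need >= 30)", "invalid_parameter")
  sigma <- stats::sd(v)
  if (sigma <= 0) ckc_stop("degenerate control matrix: zero SD", "invalid_parameter")
  structure(list(mu = mean(v), sigma = sigma, n_pooled = length(v)),
            class = "reference_distribution")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("<reference_distribution> mu = %.4f, sigma = %.4f (n = %d)\n",
              x$mu, x$sigma, x$n_pooled))
  invisible(x)
}

#' Edge z-scores against a control reference
#'
#' `z = (dPTE - mu) / sigma` per valid edge, with right-tailed normal
#' significance at `alpha`.
#'
#' @param stim Stimulation-condition `interaction_matrix`.
#' @param ref A [reference_distribution()].
#' @param alpha Right-tail significance level (default 0.01).
#' @return An `edge_zscores`: list with `z` matrix, logical `significant`
#'   matrix, `mask`, `alpha`, `parcels`.
#' @export
edge_zscores <- function(stim, ref, alpha = 0.01) {
  if (ref$sigma <= 0) ckc_stop("reference SD must be positive", "invalid_parameter")
  z <- (stim$dpte - ref$mu) / ref$sigma
  valid <- stim$mask & !is.na(stim$dpte)
  z[!valid] <- NA
  sig <- !is.na(z) & stats::pnorm(z, lower.tail = FALSE) < alpha
  structure(list(z = z, significant = sig, mask = valid, alpha = alpha,
                 parcels = stim$parcels),
            class = "edge_zscores")
}

#' Spreading Index
#'
#' Selects, within the requested hemisphere, the `n_sources` parcels with the
#' most significant outbound edges ("source nodes"; ties broken by larger
#' summed outbound z, then label order) and returns the percentage of
#' significant outbound edges among all valid outbound edges of those
#' parcels.
#'
#' @param zs An [edge_zscores()] object.
#' @param hemisphere `"left"` or `"right"` (the hemisphere to select source
#'   nodes from, i.e. contralateral or ipsilateral to stimulation).
#' @param n_sources Number of source parcels (default 4).
#' @return An `si_result`: list with `source_parcels`, `si` (percent),
#'   `n_significant`, `n_possible`, `hemisphere`, `degenerate` flag (TRUE
#'   when no edge anywhere is significant).
#' @export
spreading_index <- function(zs, hemisphere, n_sources = 4) {
  in_hemi <- zs$parcels$hemisphere == hemisphere
  if (!any(in_hemi)) ckc_stop("no parcels in requested hemisphere", "invalid_parameter")
  out_valid <- rowSums(zs$mask)
  out_sig <- rowSums(zs$significant)
  out_z <- rowSums(ifelse(is.na(zs$z), 0, zs$z))
  cand <- which(in_hemi & out_valid >= 1)
  if (length(cand) < n_sources) {
    ckc_stop("fewer hemisphere parcels with valid outbound edges than n_sources",
             "undefined_si")
  }
  ord <- cand[order(-out_sig[cand], -out_z[cand], zs$parcels$label[cand])]
  src <- ord[seq_len(n_sources)]
  n_possible <- sum(out_valid[src])
  if (n_possible == 0) ckc_stop("no valid outbound edges from source parcels", "undefined_si")
  n_significant <- sum(out_sig[src])
  structure(
    list(source_parcels = zs$parcels$label[src],
         si = 100 * n_significant / n_possible,
         n_significant = n_significant,
         n_possible = n_possible,
         hemisphere = hemisphere,
         alpha = zs$alpha,
         degenerate = sum(out_sig) == 0),
    class = "si_result"
  )
}

#' @export
print.si_result <- function(x, ...) {
  cat(sprintf("<si_result> SI = %.1f%% (%d/%d edges) from %s sources: %s%s\n",
              x$si, x$n_significant, x$n_possible, x$hemisphere,
              paste(x$source_parcels, collapse = ", "),
              if (x$degenerate) " [degenerate: no significant edges]" else ""))
  invisible(x)
}

#' @method glance si_result
#' @export
glance.si_result <- function(x, ...) {
  tibble::tibble(hemisphere = x$hemisphere, si = x$si,
                 n_significant = x$n_significant, n_possible = x$n_possible,
                 source_parcels = paste(x$source_parcels, collapse = ","),
                 degenerate = x$degenerate)
}

#' Laterality of a response metric
#'
#' `100 * contra / (contra + ipsi)`: 100 % means a completely contralateral
#' response, 50 % an equal response in both hemispheres.
#'
#' @param contra_value,ipsi_value Non-negative metric values (e.g. CKC or SI
#'   of each hemisphere).
#' @return Percent in `[0, 100]`.
#' @export
laterality <- function(contra_value, ipsi_value) {
  if (contra_value < 0 || ipsi_value < 0) {
    ckc_stop("laterality inputs must be non-negative", "invalid_parameter")
  }
  if (contra_value + ipsi_value == 0) {
    ckc_stop("laterality undefined when both values are zero", "undefined_laterality")
  }
  100 * contra_value / (contra_value + ipsi_value)
}

#' Symmetry of a response metric across stimulation sides
#'
#' `100 * min / max` of the two sides; 100 % means identical responses.
#'
#' @param left_value,right_value Non-negative metric values.
#' @return Percent in `[0, 100]`.
#' @export
symmetry <- function(left_value, right_value) {
  if (left_value < 0 || right_value < 0) {
    ckc_stop("symmetry inputs must be non-negative", "invalid_parameter")
  }
  if (max(left_value, right_value) == 0) {
    ckc_stop("symmetry undefined when both values are zero", "undefined_symmetry")
  }
  100 * min(left_value, right_value) / max(left_value, right_value)
}

#' Hemispheric CKC value and laterality from a detection result
#'
#' Summarizes a `ckc_result` per hemisphere (midline channels excluded) with
#' either the maximum (default) or mean channel CKC, and returns the
#' laterality of the hemisphere contralateral to the stimulated side.
#'
#' @param result A `ckc_result`.
#' @param stim_side `"left"` or `"right"` stimulated hand.
#' @param statistic `"max"` (default) or `"mean"`.
#' @return A tibble with `contra`, `ipsi` and `laterality`.
#' @export
ckc_laterality <- function(result, stim_side, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  hemi <- channel_hemisphere(result$channels$channel)
  agg <- function(side) {
    v <- result$channels$ckc[hemi == side]
    if (length(v) == 0) ckc_stop("no channels in hemisphere", "invalid_parameter")
    if (statistic == "max") max(v) else mean(v)
  }
  contra_side <- if (stim_side == "left") "right" else "left"
  contra <- agg(contra_side); ipsi <- agg(stim_side)
  tibble::tibble(contra = contra, ipsi = ipsi,
                 laterality = laterality(contra, ipsi))
}
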