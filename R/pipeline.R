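# End-to-end pipelines: raw recording -> CKC detection report, and parcel
# signals -> dPTE / Spreading Index / Consistent Network. One config object
# governs both; all randomness flows from its seed.

#' Pipeline configuration
#'
#' Collects every tunable of the detection and network pipelines with the
#' standard defaults. Serializes losslessly to JSON.
#'
#' @param ... Named overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter_low = 0.5, filter_high = 30, filter_order = 5, target_fs = 250,
    epoch_pre = 200, epoch_post = 900, reject_uv = 250,
    csd_m = 3, csd_lambda = 0, csd_legendre = 50, csd_head_radius = 0.092,
    wavelet_fmin = 0.5, wavelet_fmax = 12, wavelet_bins = 40,
    response_freq = 3.56, n_cycles = 7,
    alpha = 0.01, fdr_q = 0.01, edge_exclusion = 200,
    pte_center = 3.56, pte_halfwidth = 0.3, pte_fir_order = 626,
    pte_delay = "auto", pte_bins = "scott",
    cn_k = 0.05, cn_alpha = 0.05,
    si_alpha = 0.01, si_n_sources = 4,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    ckc_stop(paste0("unknown config field(s): ", paste(bad, collapse = ", ")),
             "invalid_parameter")
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @return `save_config` returns `path` invisibly; `load_config` a
#'   `pipeline_config`.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the scalp CKC detection pipeline
#'
#' Preprocessing (zero-phase band-pass, resampling, trigger-locked epoching,
#' amplitude rejection), CSD transform, wavelet phase decomposition at the
#' pinned response bin, ITC, the CKC metric with Rayleigh significance and
#' BH-FDR across channels.
#'
#' @param recording An `eeg_recording` (or path readable by
#'   [read_recording()]) with triggers.
#' @param config A [pipeline_config()].
#' @param max_epochs Optionally cap the number of (earliest) epochs analysed.
#' @param freq_mode `"pinned"` (default) or `"full"` (all wavelet bins, for
#'   t-f maps).
#' @param out_dir Optional directory for the per-channel CSV and JSON
#'   summary report.
#' @return A `ckc_result`; the preprocessed epochs are attached as the
#'   `epochs` attribute.
#' @export
run_detection_pipeline <- function(recording, config = pipeline_config(),
                                   max_epochs = NULL, freq_mode = "pinned",
                                   out_dir = NULL) {
  if (is.character(recording)) recording <- read_recording(recording)
  if (length(recording$trigger_times) == 0) {
    ckc_stop("recording has no triggers", "no_trigger")
  }
  rec <- filter_and_resample(recording, low = config$filter_low,
                             high = config$filter_high,
                             order = config$filter_order,
                             target_fs = config$target_fs)
  ep <- epoch_recording(rec, pre = config$epoch_pre, post = config$epoch_post)
  ep <- reject_epochs(ep, config$reject_uv)
  if (!is.null(max_epochs) && n_epochs(ep) > max_epochs) {
    keep <- seq_len(max_epochs)
    ep$data <- ep$data[keep, , , drop = FALSE]
    ep$kept_trigger_indices <- ep$kept_trigger_indices[keep]
    ep$trigger_times <- ep$trigger_times[keep]
  }
  ep <- csd(ep, m = config$csd_m, lambda = config$csd_lambda,
            n_legendre = config$csd_legendre,
            head_radius = config$csd_head_radius)
  bank <- build_wavelet_bank(ep$fs, fmin = config$wavelet_fmin,
                             fmax = config$wavelet_fmax,
                             n_bins = config$wavelet_bins,
                             pinned = config$response_freq,
                             n_cycles = config$n_cycles)
  phases <- wavelet_phase(ep, bank,
                          frequencies = if (identical(freq_mode, "full")) "all" else "pinned")
  res <- ckc_metric(phases, response_freq = config$response_freq,
                    edge_exclusion = config$edge_exclusion,
                    alpha = config$alpha, fdr_q = config$fdr_q,
                    keep_itc_map = identical(freq_mode, "full"))
  attr(res, "epochs") <- ep
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$channels, file.path(out_dir, "ckc_channels.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(as.list(glance(res)), list(config = unclass(config))),
      file.path(out_dir, "ckc_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Run the source-space network pipeline
#'
#' For every subject: narrowband phase extraction, dPTE interaction matrix
#' and fidelity masking; with a control matrix, the control-referenced edge
#' z-scores and Spreading Index; with two or more subjects, the group
#' Consistent Network.
#'
#' @param stim_list List of `parcel_signals`, one per subject (stimulation
#'   condition).
#' @param control_list Optional list of control-condition `parcel_signals`
#'   (entries may be `NULL`; SI is then skipped for that subject with a
#'   warning).
#' @param hemisphere Hemisphere for SI source-node selection.
#' @param mask Optional fidelity mask.
#' @param config A [pipeline_config()].
#' @return List with `matrices`, `control_matrices`, `si` (tibble, one row
#'   per subject with an SI) and `cn` (a `consistent_network`, or `NULL`
#'   for a single subject).
#' @export
run_network_pipeline <- function(stim_list, control_list = NULL,
                                 hemisphere = "left", mask = NULL,
                                 config = pipeline_config()) {
  if (length(stim_list) == 0) ckc_stop("empty subject list", "invalid_parameter")
  mk <- function(p) dpte_matrix(p, mask = mask, delay = config$pte_delay,
                                n_bins = config$pte_bins,
                                center = config$pte_center,
                                halfwidth = config$pte_halfwidth,
                                fir_order = config$pte_fir_order)
  matrices <- lapply(stim_list, mk)
  control_matrices <- if (is.null(control_list)) {
    vector("list", length(stim_list))
  } else {
    lapply(control_list, function(p) if (is.null(p)) NULL else mk(p))
  }

  si_rows <- list()
  for (s in seq_along(matrices)) {
    if (is.null(control_matrices[[s]])) {
      warning(sprintf("subject %d: no control recording, SI skipped", s))
      next
    }
    ref <- reference_distribution(control_matrices[[s]])
    zs <- edge_zscores(matrices[[s]], ref, alpha = config$si_alpha)
    si <- spreading_index(zs, hemisphere, n_sources = config$si_n_sources)
    si_rows[[length(si_rows) + 1]] <-
      dplyr::bind_cols(tibble::tibble(subject = s), glance(si))
  }
  cn <- if (length(matrices) >= 2) {
    consistent_network(matrices, k = config$cn_k, alpha = config$cn_alpha)
  } else NULL

  list(matrices = matrices, control_matrices = control_matrices,
       si = dplyr::bind_rows(si_rows), cn = cn)
}
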