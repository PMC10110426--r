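# ggplot2 visualizations for the main result types.

#' @method autoplot ckc_result
#' @export
autoplot.ckc_result <- function(object, ...) {
  df <- object$channels
  df$channel <- factor(df$channel, levels = df$channel)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$ckc,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#c0392b")) +
    ggplot2::labs(x = NULL, y = "CKC",
                  title = sprintf("CKC at %.2f Hz (%s, %d epochs)",
                                  object$response_freq, object$method,
                                  object$n_epochs)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @method autoplot interaction_matrix
#' @export
autoplot.interaction_matrix <- function(object, ...) {
  df <- tidy(object)
  lv <- object$parcels$label
  df$source <- factor(df$source, levels = lv)
  df$target <- factor(df$target, levels = rev(lv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$target,
                                   fill = .data$dpte)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "#2c7bb6",
                                  mid = "white", high = "#d7191c") +
    ggplot2::labs(x = "source parcel", y = "target parcel", fill = "dPTE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @method autoplot consistent_network
#' @export
autoplot.consistent_network <- function(object, ...) {
  df <- object$edges[object$edges$count > 0, ]
  lv <- object$parcels$label
  df$source <- factor(df$source, levels = lv)
  df$target <- factor(df$target, levels = rev(lv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$target)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count / object$n_subjects)) +
    ggplot2::geom_point(data = df[df$significant, ], size = 0.6) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "consistency", x = "source", y = "target",
                  title = sprintf("Consistent network (k = %g, alpha = %g)",
                                  object$k, object$alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot an epoch-count detection sweep
#'
#' @param sweep Tibble from [epoch_count_sweep()].
#' @return A ggplot object: peak CKC vs epoch count, detection state coloured.
#' @export
plot_epoch_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$n_epochs, y = .data$peak_ckc)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$any_significant), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "#c0392b")) +
    ggplot2::labs(x = "epochs analysed", y = "peak-channel CKC",
                  colour = "detected") +
    ggplot2::theme_minimal()
}
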