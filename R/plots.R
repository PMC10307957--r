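#' Plot a gaze trace
#'
#' Horizontal gaze position over time for one or more trials, with the
#' target onset marked.
#'
#' @param trace Gaze tibble (one or a few trials).
#' @param target_onset Target onset in ms.
#' @return A ggplot object.
#' @export
plot_gaze_trace <- function(trace, target_onset = 1000) {
  facet <- intersect(c("condition", "block", "trial"), names(trace))
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$t_ms, y = .data$x_deg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = target_onset, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(-10, 0, 10), linetype = "dotted",
                        colour = "grey70") +
    ggplot2::labs(x = "Time (ms)", y = "Horizontal gaze (deg)")
  if (length(facet)) {
    p <- p + ggplot2::facet_wrap(facet, labeller = ggplot2::label_both)
  }
  p
}

#' @rdname autoplot.em_benchmark
#' @export
plot_benchmark <- function(object, metric = c("auroc", "cv_auroc_mean"), ...) {
  metric <- match.arg(metric)
  df <- tidy.em_benchmark(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_set, y = .data$algorithm,
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data[[metric]])),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0.5, 1), oob = scales_squish) +
    ggplot2::labs(x = "Feature set", y = "Algorithm", fill = toupper(metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

# minimal squish to avoid a scales dependency at the package surface
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Heatmap of benchmark results
#'
#' @param object An `em_benchmark` from [run_all()].
#' @param metric Which AUROC to display: held-out test (`"auroc"`) or the
#'   cross-validated mean.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.em_benchmark <- function(object, metric = c("auroc", "cv_auroc_mean"), ...) {
  plot_benchmark(object, metric = metric, ...)
}

#' ROC curves of the benchmark's cells
#'
#' @param object An `em_benchmark` from [run_all()].
#' @param cells Optional character vector of `"algorithm|feature_set"`
#'   keys; defaults to the best algorithm per feature set.
#' @return A ggplot object.
#' @export
plot_roc <- function(object, cells = NULL) {
  rocs <- attr(object, "roc")
  if (is.null(cells)) {
    best <- glance.em_benchmark(object)
    cells <- paste(best$algorithm, best$feature_set, sep = "|")
  }
  df <- purrr::map_dfr(cells, function(key) {
    dplyr::mutate(rocs[[key]], cell = key)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$cell)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of permutation importances
#'
#' @param importance Tibble from [permutation_importance()].
#' @param top_n Number of features shown (default 5).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 5L) {
  df <- dplyr::slice_min(importance, .data$rank, n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_auroc_drop,
                                   y = stats::reorder(.data$feature,
                                                      .data$mean_auroc_drop))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean AUROC drop when permuted", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
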