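# ggplot2 visualizations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an FC matrix
#'
#' @param object An [fc_matrix].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_matrix <- function(object, ...) {
  p <- nrow(object)
  df <- tidyr::expand_grid(i = seq_len(p), j = seq_len(p))
  df$weight <- as.vector(t(as.matrix(object)))
  lim <- max(abs(df$weight))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b",
                                  limits = c(-lim, lim)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s FC", attr(object, "method")),
                  x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal()
}

#' Cross-validated R-squared profile of a hyperparameter selection
#'
#' @param object An `fc_selection`.
#' @param ... Unused.
#' @return A ggplot of mean held-out R-squared against the hyperparameter,
#'   with the selected value marked.
#' @export
autoplot.fc_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$selected, ], color = "#b2182b",
                        size = 2) +
    ggplot2::labs(x = sprintf("%s hyperparameter", object$method),
                  y = "mean held-out R²") +
    ggplot2::theme_minimal()
}

#' Benchmark metric distributions by method
#'
#' @param object An `fc_benchmark`.
#' @param ... Unused.
#' @return A ggplot: per-network metric values as boxplots, one facet per
#'   metric.
#' @export
autoplot.fc_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Sweep performance curves
#'
#' @param object An `fc_sweep`.
#' @param metric `"gt_similarity"` or `"hyperparameter"`.
#' @param ... Unused.
#' @return A ggplot of condition means against timepoints (log scale),
#'   one line per noise level, faceted by method.
#' @export
autoplot.fc_sweep <- function(object, metric = c("gt_similarity",
                                                 "hyperparameter"), ...) {
  metric <- match.arg(metric)
  ycol <- if (metric == "gt_similarity") "mean_gt_similarity" else
    "mean_hyperparameter"
  df <- object$condition_means
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_timepoints,
                                   y = .data[[ycol]],
                                   color = factor(.data$noise_level))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "timepoints", y = ycol, color = "noise") +
    ggplot2::theme_minimal()
}

#' Predicted versus actual outcome scatter
#'
#' @param object An `fc_prediction`.
#' @param ... Unused.
#' @return A ggplot with the identity line and pooled accuracy annotated.
#' @export
autoplot.fc_prediction <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_abline(linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = sprintf("%s: pooled r = %.3f", object$outcome,
                                  object$accuracy),
                  x = "actual", y = "predicted") +
    ggplot2::theme_minimal()
}
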