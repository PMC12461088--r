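# broom-style tidiers for the package's result objects.

#' Tidy an FC matrix into an edge table
#'
#' @param x An [fc_matrix].
#' @param ... Unused.
#' @return Tibble with one row per strict upper-triangle edge: `edge`,
#'   `i`, `j`, `weight`, `method`.
#' @export
tidy.fc_matrix <- function(x, ...) {
  dplyr::mutate(upper_tri_index(nrow(x)),
                weight = upper_tri_vec(as.matrix(x)),
                method = attr(x, "method"))
}

#' Tidy a ground-truth network into a directed edge table
#'
#' @param x An [fc_network][generate_network].
#' @param ... Unused.
#' @return Tibble with one row per directed nonzero edge: `from`, `to`,
#'   `weight`, `intra_modular`.
#' @export
tidy.fc_network <- function(x, ...) {
  idx <- which(x$weights != 0, arr.ind = TRUE)
  tibble::tibble(from = idx[, 2], to = idx[, 1],
                 weight = x$weights[idx],
                 intra_modular = x$module[idx[, 1]] == x$module[idx[, 2]])
}

#' Tidy a hyperparameter selection profile
#'
#' @param x An `fc_selection` from [select_hyperparameter()].
#' @param ... Unused.
#' @return Tibble with `value`, `mean_r2`, `selected`.
#' @export
tidy.fc_selection <- function(x, ...) {
  tibble::tibble(value = x$grid, mean_r2 = x$mean_r2_per_value,
                 selected = x$grid == x$best_value)
}

#' @export
glance.fc_selection <- function(x, ...) {
  tibble::tibble(method = x$method, best_value = x$best_value,
                 best_r2 = max(x$mean_r2_per_value),
                 n_grid = length(x$grid), fold_count = x$fold_count,
                 expansions = x$expansions, boundary = x$boundary)
}

#' Tidy a prediction report
#'
#' @param x An `fc_prediction` from [predict_outcome()].
#' @param ... Unused.
#' @return Tibble with per-subject `actual`, `predicted`, `fold`.
#' @export
tidy.fc_prediction <- function(x, ...) {
  tibble::tibble(subject = seq_along(x$predicted), actual = x$actual,
                 predicted = x$predicted, fold = x$fold)
}

#' @export
glance.fc_prediction <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, accuracy = x$accuracy,
                 n = length(x$predicted), n_folds = length(x$lambda_per_fold),
                 confound = x$confound %||% NA_character_)
}

#' Tidy per-edge QC-FC results
#'
#' @param x An `fc_qcfc` from [qcfc()].
#' @param ... Unused.
#' @return The per-edge tibble (`edge`, `i`, `j`, `r`, `p`, `p_adj`,
#'   `n_used`).
#' @export
tidy.fc_qcfc <- function(x, ...) x$edges

#' @export
glance.fc_qcfc <- function(x, ...) {
  tibble::tibble(n_edges_tested = x$n_edges_tested,
                 prop_significant = x$prop_significant,
                 median_abs_qcfc = x$median_abs_qcfc,
                 alpha = x$alpha, nonzero_control = x$nonzero_control)
}

#' Tidy benchmark results
#'
#' @param x An `fc_benchmark` from [run_main_benchmark()].
#' @param ... Unused.
#' @return The long results tibble (`network`, `method`, `metric`,
#'   `value`).
#' @export
tidy.fc_benchmark <- function(x, ...) x$results

#' @export
glance.fc_benchmark <- function(x, ...) {
  s <- dplyr::summarise(
    dplyr::group_by(x$results, .data$method, .data$metric),
    mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
  tidyr::pivot_wider(s, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' Tidy sweep results
#'
#' @param x An `fc_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return The per-condition tibble.
#' @export
tidy.fc_sweep <- function(x, ...) x$conditions

#' @export
glance.fc_sweep <- function(x, ...) x$spearman
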