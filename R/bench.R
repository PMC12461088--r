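#' Benchmark configuration
#'
#' Bundles every knob of the simulation benchmarks.  The shipped defaults
#' are a scaled-down design (10 networks x 20 sessions) chosen so a full
#' run completes in minutes on one CPU; the full-scale study design (50
#' networks x 100 sessions x 250 timepoints at noise 0.5, and a sweep over
#' {50, 100, 200, 300, 400, 500, 1000, 10000} timepoints x {0.25, 0.5, 1}
#' noise) is obtained by overriding `n_networks`, `n_sessions`,
#' `sweep_timepoints` and `sweep_noise_levels`.
#'
#' @param n_networks Number of ground-truth networks.
#' @param n_sessions Sessions simulated per network (main benchmark).
#' @param n_timepoints Timepoints per session (main benchmark).
#' @param noise_level Measurement-noise ratio (main benchmark).
#' @param methods FC estimators to run.
#' @param network Named list of overrides passed to [generate_network()].
#' @param grids Named list of per-method initial hyperparameter grids for
#'   [select_hyperparameter()].
#' @param sweep_timepoints,sweep_noise_levels Conditions of the
#'   data-quantity x noise sweep ([run_sweep()]).
#' @param n_folds Cross-validation folds for hyperparameter selection.
#' @param seed Master seed; all network/session seeds derive from it.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_networks = 10, n_sessions = 20,
                             n_timepoints = 250, noise_level = 0.5,
                             methods = c("pairwise", "partial", "glasso",
                                         "gridge", "pcreg"),
                             network = list(), grids = list(),
                             sweep_timepoints = c(50, 100, 200, 300, 400,
                                                  500, 1000, 10000),
                             sweep_noise_levels = c(0.25, 0.5, 1),
                             n_folds = 10, seed = 1L) {
  stopifnot(n_networks >= 1, n_sessions >= 1, n_timepoints >= 2)
  structure(list(n_networks = n_networks, n_sessions = n_sessions,
                 n_timepoints = n_timepoints, noise_level = noise_level,
                 methods = methods, network = network, grids = grids,
                 sweep_timepoints = sweep_timepoints,
                 sweep_noise_levels = sweep_noise_levels,
                 n_folds = n_folds, seed = seed),
            class = "benchmark_config")
}

# Deterministic seeds: networks and sessions are independent reproducible
# streams keyed by (master seed, network index, session index, condition).
# Main benchmark and sweep share network seeds for a given master seed, so
# a degenerate single-condition sweep reproduces the main benchmark; the
# study's "additional networks" for the sweep come from a different master
# seed.
bench_network_seed <- function(seed, k) {
  child_seed(seed, 500000000 + k)
}
bench_session_seed <- function(seed, k, s, cond = 1L) {
  # double arithmetic: the index can exceed .Machine$integer.max and
  # child_seed reduces it mod 2^31 - 1
  child_seed(seed, ((as.numeric(cond) - 1) * 1000 + k) * 100000 + s)
}

# Selection + estimation for one session; returns fc and hyperparameter.
estimate_with_selection <- function(sess, method, cfg) {
  if (method %in% c("pairwise", "partial")) {
    return(list(fc = estimate_fc(sess, method), hyper = NA_real_))
  }
  sel <- select_hyperparameter(sess, method,
                               initial_grid = cfg$grids[[method]],
                               n_folds = cfg$n_folds)
  list(fc = estimate_fc(sess, method, sel$best_value),
       hyper = sel$best_value)
}

#' Run the main simulation benchmark
#'
#' For each generated network, simulates `n_sessions` independent sessions,
#' selects hyperparameters and estimates FC per session for every method,
#' and computes the three headline metrics: between-session similarity
#' (sessions 1 vs 2), ground-truth similarity of the session-averaged FC
#' (validity), and ground-truth similarity of the session-1 FC (individual
#' accuracy).  Ground truth is the symmetrized generating weight matrix.
#'
#' @param config A [benchmark_config()].
#' @param progress Print one line per network?
#' @return An `fc_benchmark`: list with `results` (tibble: `network`,
#'   `method`, `metric`, `value`), `hyperparameters` (tibble: `network`,
#'   `session`, `method`, `value`) and `config`.  Use
#'   [compare_methods_table()] on a metric slice for the paired Fisher-z
#'   comparisons.
#' @export
run_main_benchmark <- function(config, progress = FALSE) {
  cfg <- config
  res <- list(); hyp <- list()
  for (k in seq_len(cfg$n_networks)) {
    net <- do.call(generate_network,
                   c(list(seed = bench_network_seed(cfg$seed, k)),
                     cfg$network))
    truth <- symmetrize(net$weights)
    fc_sum <- lapply(cfg$methods, function(m) matrix(0, net$meta$p,
                                                     net$meta$p))
    names(fc_sum) <- cfg$methods
    fc1 <- list(); fc2 <- list()
    for (s in seq_len(cfg$n_sessions)) {
      sess <- simulate_session(net, cfg$n_timepoints, cfg$noise_level,
                               seed = bench_session_seed(cfg$seed, k, s))
      for (m in cfg$methods) {
        fit <- tryCatch(
          estimate_with_selection(sess, m, cfg),
          error = function(e) {
            stop(sprintf(
              "benchmark stage failed [network %d (seed %d), session %d (seed %d), method %s]: %s",
              k, net$meta$seed, s, sess$seed, m, conditionMessage(e)),
              call. = FALSE)
          })
        fc_sum[[m]] <- fc_sum[[m]] + fc_values(fit$fc)
        if (s == 1) fc1[[m]] <- fit$fc
        if (s == 2) fc2[[m]] <- fit$fc
        if (!is.na(fit$hyper)) {
          hyp[[length(hyp) + 1]] <- tibble::tibble(
            network = k, session = s, method = m, value = fit$hyper)
        }
      }
    }
    for (m in cfg$methods) {
      rows <- tibble::tibble(
        network = k, method = m,
        metric = c("gt_network_avg", "gt_individual"),
        value = c(target_similarity(fc_sum[[m]] / cfg$n_sessions, truth),
                  target_similarity(fc1[[m]], truth)))
      if (cfg$n_sessions >= 2) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          network = k, method = m, metric = "between_session",
          value = between_session_similarity(fc1[[m]], fc2[[m]])))
      }
      res[[length(res) + 1]] <- rows
    }
    if (progress) {
      message(sprintf("network %d/%d done", k, cfg$n_networks))
    }
  }
  structure(list(results = dplyr::bind_rows(res),
                 hyperparameters = dplyr::bind_rows(hyp),
                 config = cfg),
            class = "fc_benchmark")
}

#' Run the data-quantity by noise-level sweep
#'
#' Simulates one session per network for every combination of
#' `sweep_timepoints` and `sweep_noise_levels` (pass a different master
#' seed to use networks distinct from the main benchmark's), estimates FC
#' with per-session hyperparameter
#' selection, and records the ground-truth similarity of each individual
#' estimate together with the selected hyperparameter.  Unregularized
#' partial correlation cannot run when a condition has no more timepoints
#' than nodes; those cells are recorded as `NA` with an
#' "insufficient data" note rather than aborting.  Condition means and
#' Spearman rank correlations of the mean selected hyperparameter against
#' timepoints and against noise level are attached.
#'
#' @inheritParams run_main_benchmark
#' @return An `fc_sweep`: list with `conditions` (per network x condition
#'   x method tibble), `condition_means`, `spearman` (per method and
#'   factor) and `config`.
#' @export
run_sweep <- function(config, progress = FALSE) {
  cfg <- config
  grid <- tidyr::expand_grid(n_timepoints = cfg$sweep_timepoints,
                             noise_level = cfg$sweep_noise_levels)
  rows <- list()
  for (k in seq_len(cfg$n_networks)) {
    net <- do.call(generate_network,
                   c(list(seed = bench_network_seed(cfg$seed, k)),
                     cfg$network))
    truth <- symmetrize(net$weights)
    for (ci in seq_len(nrow(grid))) {
      sess <- simulate_session(net, grid$n_timepoints[ci],
                               grid$noise_level[ci],
                               seed = bench_session_seed(cfg$seed, k, 1L,
                                                         cond = ci))
      for (m in cfg$methods) {
        fit <- tryCatch(
          estimate_with_selection(sess, m, cfg),
          error = function(e) {
            if (grepl("insufficient data", conditionMessage(e))) {
              NULL
            } else {
              stop(sprintf(
                "sweep stage failed [network %d, T=%d, noise=%g, method %s]: %s",
                k, grid$n_timepoints[ci], grid$noise_level[ci], m,
                conditionMessage(e)), call. = FALSE)
            }
          })
        rows[[length(rows) + 1]] <- tibble::tibble(
          network = k, n_timepoints = grid$n_timepoints[ci],
          noise_level = grid$noise_level[ci], method = m,
          hyperparameter = if (is.null(fit)) NA_real_ else fit$hyper,
          gt_similarity = if (is.null(fit)) NA_real_ else
            target_similarity(fit$fc, truth),
          note = if (is.null(fit)) "insufficient data" else NA_character_)
      }
    }
    if (progress) {
      message(sprintf("sweep network %d/%d done", k, cfg$n_networks))
    }
  }
  conditions <- dplyr::bind_rows(rows)
  means <- dplyr::summarise(
    dplyr::group_by(conditions, .data$n_timepoints, .data$noise_level,
                    .data$method),
    mean_hyperparameter = mean(.data$hyperparameter, na.rm = TRUE),
    mean_gt_similarity = mean(.data$gt_similarity, na.rm = TRUE),
    sd_gt_similarity = sd(.data$gt_similarity, na.rm = TRUE),
    n_ok = sum(!is.na(.data$gt_similarity)), .groups = "drop")
  regular <- intersect(cfg$methods, c("glasso", "gridge", "pcreg"))
  spearman <- purrr::map_dfr(regular, function(m) {
    mm <- dplyr::filter(means, .data$method == m,
                        is.finite(.data$mean_hyperparameter))
    tibble::tibble(
      method = m,
      versus = c("n_timepoints", "noise_level"),
      rho = c(cor(mm$mean_hyperparameter, mm$n_timepoints,
                  method = "spearman"),
              cor(mm$mean_hyperparameter, mm$noise_level,
                  method = "spearman")))
  })
  structure(list(conditions = conditions, condition_means = means,
                 spearman = spearman, config = cfg),
            class = "fc_sweep")
}

#' @export
print.fc_benchmark <- function(x, ...) {
  cat(sprintf("<fc_benchmark> %d networks x %d sessions, methods: %s\n",
              x$config$n_networks, x$config$n_sessions,
              paste(x$config$methods, collapse = ", ")))
  s <- dplyr::summarise(
    dplyr::group_by(x$results, .data$method, .data$metric),
    mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
  print(tidyr::pivot_wider(s, names_from = "metric",
                           values_from = c("mean", "sd")))
  invisible(x)
}

#' @export
print.fc_sweep <- function(x, ...) {
  cat(sprintf("<fc_sweep> %d networks x %d conditions, methods: %s\n",
              x$config$n_networks,
              length(x$config$sweep_timepoints) *
                length(x$config$sweep_noise_levels),
              paste(x$config$methods, collapse = ", ")))
  print(x$spearman)
  invisible(x)
}
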