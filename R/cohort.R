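#' Planted-effect specification for synthetic cohorts
#'
#' Describes which edges of a synthetic cohort carry covariate effects and
#' how strong they are, so that downstream QC-FC and prediction analyses
#' have a known recovery target.
#'
#' @param n_motion_edges Number of edges whose weights are shifted in
#'   proportion to (standardized) subject motion.
#' @param motion_beta Per-standard-deviation shift added to those edges.
#' @param n_outcome_edges Number of edges whose summed weights define the
#'   noiseless outcome signal.
#' @param outcome_noise_sd SD of Gaussian noise added to the standardized
#'   outcome signal; the resulting correlation between outcome and signal
#'   is `1 / sqrt(1 + outcome_noise_sd^2)` in expectation.
#' @return A `planted_effects` list.
#' @export
planted_effects <- function(n_motion_edges = 0, motion_beta = 0,
                            n_outcome_edges = 0, outcome_noise_sd = 0.5) {
  stopifnot(n_motion_edges >= 0, n_outcome_edges >= 0,
            outcome_noise_sd >= 0)
  structure(list(n_motion_edges = n_motion_edges, motion_beta = motion_beta,
                 n_outcome_edges = n_outcome_edges,
                 outcome_noise_sd = outcome_noise_sd),
            class = "planted_effects")
}

#' Generate a synthetic cohort of FC matrices with covariates
#'
#' Stands in for an empirical multi-subject dataset: each subject's
#' connectivity is a jittered copy of a shared ground-truth network, a
#' session is simulated from it, and FC is estimated with the requested
#' method.  Subject covariates (motion in mm, age in years, binary sex and
#' a continuous outcome) are then drawn, and the effects described by
#' `planted` are injected: motion-related edges receive a weight shift
#' proportional to standardized motion, and the outcome is a standardized
#' sum of designated edge weights plus Gaussian noise.  The realized edge
#' indices and the noiseless signal are recorded for recovery tests.
#'
#' @param base_net An [fc_network][generate_network] shared by the cohort.
#' @param n_subjects Number of subjects (>= 3).
#' @param planted A [planted_effects()] specification.
#' @param n_timepoints,noise_level Session simulation parameters.
#' @param method,param FC estimator applied per subject (pairwise by
#'   default; it is the cheapest and reliability is irrelevant here).
#' @param w_jitter_sd Between-subject SD of edge-weight jitter, as a
#'   fraction of the SD of nonzero ground-truth weights.
#' @param seed Integer seed.
#' @return An `fc_cohort`: list with `fc` (per-subject [fc_matrix]),
#'   `covariates` (tibble: `id`, `motion`, `age`, `sex`, `outcome`),
#'   `planted` (specification plus realized edge indices and signal) and
#'   `meta`.
#' @export
generate_cohort <- function(base_net, n_subjects, planted = planted_effects(),
                            n_timepoints = 250, noise_level = 0.5,
                            method = "pairwise", param = NULL,
                            w_jitter_sd = 0.1, seed = 1L) {
  stopifnot(inherits(base_net, "fc_network"), n_subjects >= 3)
  p <- base_net$meta$p
  n_edges <- p * (p - 1) / 2
  stopifnot(planted$n_motion_edges <= n_edges,
            planted$n_outcome_edges <= n_edges)
  set.seed(child_seed(seed, 0L))
  motion <- rlnorm(n_subjects, meanlog = log(0.12), sdlog = 0.4)
  age <- runif(n_subjects, 36, 90)
  sex <- rbinom(n_subjects, 1, 0.5)
  if (planted$motion_beta != 0 && var(motion) == 0) {
    stop("degenerate effect specification: motion covariate has zero ",
         "variance", call. = FALSE)
  }
  motion_edges <- sort(sample.int(n_edges, planted$n_motion_edges))
  outcome_edges <- sort(sample.int(n_edges, planted$n_outcome_edges))

  w_sd <- sd(base_net$weights[base_net$weights != 0])
  edge_mask <- base_net$weights != 0
  fc <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(child_seed(seed, s))
    w_s <- base_net$weights
    w_s[edge_mask] <- w_s[edge_mask] +
      rnorm(sum(edge_mask), 0, w_jitter_sd * w_sd)
    net_s <- base_net
    net_s$weights <- w_s
    sess <- simulate_session(net_s, n_timepoints, noise_level,
                             seed = child_seed(seed, 100000L + s))
    fc[[s]] <- estimate_fc(sess, method, param)
  }

  if (planted$n_motion_edges > 0 && planted$motion_beta != 0) {
    mz <- as.vector(scale(motion))
    for (s in seq_len(n_subjects)) {
      v <- upper_tri_vec(fc[[s]])
      v[motion_edges] <- v[motion_edges] + planted$motion_beta * mz[s]
      m <- matrix(0, p, p)
      m[upper.tri(m)] <- v
      fc[[s]] <- fc_matrix(m + t(m), method = attr(fc[[s]], "method"),
                           hyperparameter = attr(fc[[s]], "hyperparameter"))
    }
  }

  if (planted$n_outcome_edges > 0) {
    signal <- vapply(fc, function(m) sum(upper_tri_vec(m)[outcome_edges]),
                     numeric(1))
    if (var(signal) == 0) {
      stop("degenerate effect specification: outcome signal has zero ",
           "variance", call. = FALSE)
    }
    signal_z <- as.vector(scale(signal))
    set.seed(child_seed(seed, 200000L))
    outcome <- signal_z + rnorm(n_subjects, 0, planted$outcome_noise_sd)
  } else {
    set.seed(child_seed(seed, 200000L))
    signal_z <- NULL
    outcome <- rnorm(n_subjects)
  }

  planted$motion_edges <- motion_edges
  planted$outcome_edges <- outcome_edges
  planted$outcome_signal <- signal_z
  structure(list(
    fc = fc,
    covariates = tibble::tibble(id = seq_len(n_subjects), motion = motion,
                                age = age, sex = sex, outcome = outcome),
    planted = planted,
    meta = list(n_subjects = n_subjects, p = p, method = method,
                n_timepoints = n_timepoints, noise_level = noise_level,
                w_jitter_sd = w_jitter_sd, seed = seed)),
    class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("<fc_cohort> %d subjects x %d nodes (%s FC)\n",
              x$meta$n_subjects, x$meta$p, x$meta$method))
  invisible(x)
}
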