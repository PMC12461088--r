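#' Between-session similarity (test-retest reliability)
#'
#' Pearson correlation of the vectorized strict upper triangles of two FC
#' matrices estimated from repeated sessions of the same subject or
#' simulated network.  High values indicate that edge estimates are stable
#' against sampling noise.
#'
#' @param fc_a,fc_b Square matrices of matching dimension.
#' @return Pearson r.
#' @export
between_session_similarity <- function(fc_a, fc_b) {
  stopifnot(all(dim(fc_a) == dim(fc_b)))
  cor(upper_tri_vec(as.matrix(fc_a)), upper_tri_vec(as.matrix(fc_b)))
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' `ICC = (BMS - WMS) / (BMS + (k - 1) WMS)` from the one-way ANOVA mean
#' squares of a subjects-by-sessions table: `BMS` is the between-subject
#' mean square and `WMS` the within-subject mean square.  Values near 1
#' indicate that between-subject differences dominate session noise; pure
#' noise gives ICCs distributed around 0.
#'
#' @param x Numeric subjects x sessions matrix (k >= 2 sessions) for a
#'   single edge.
#' @return ICC(1,1) scalar.
#' @export
icc_1_1 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 2, k >= 2)
  mi <- rowMeans(x)
  bms <- k * sum((mi - mean(x))^2) / (n - 1)
  wms <- sum((x - mi)^2) / (n * (k - 1))
  (bms - wms) / (bms + (k - 1) * wms)
}

#' Per-edge ICC(1,1) across two sessions
#'
#' Vectorized [icc_1_1()] over every upper-triangle edge of per-subject FC
#' matrices from two repeated sessions.
#'
#' @param fc_session1,fc_session2 Lists of per-subject FC matrices.
#' @return Tibble with `edge`, `i`, `j`, `icc`.
#' @export
icc_per_edge <- function(fc_session1, fc_session2) {
  stopifnot(length(fc_session1) == length(fc_session2),
            length(fc_session1) >= 2)
  a <- do.call(rbind, lapply(fc_session1, upper_tri_vec))
  b <- do.call(rbind, lapply(fc_session2, upper_tri_vec))
  n <- nrow(a)
  mi <- (a + b) / 2
  grand <- colMeans(mi)
  bms <- 2 * colSums(sweep(mi, 2, grand)^2) / (n - 1)
  wms <- colSums((a - mi)^2 + (b - mi)^2) / n
  p <- nrow(fc_session1[[1]])
  dplyr::mutate(upper_tri_index(p), icc = (bms - wms) / (bms + wms))
}

#' Edges systematically assigned strong weights by every method
#'
#' Selects, for each method's group-averaged FC matrix, the edges whose
#' absolute weight reaches that method's given percentile, and intersects
#' the sets across methods.  Used to restrict per-edge reliability
#' analyses to edges that all methods treat as nonzero, removing the
#' automatic ICC penalty on the null edges of sparse estimators.
#'
#' @param group_mean_fc Named list of group-averaged FC matrices, one per
#'   method, of identical dimension.
#' @param percentile Percentile of absolute weight (default 98).
#' @return Sorted integer vector of upper-triangle edge indices (see
#'   [upper_tri_index()] for the node-pair mapping).
#' @export
select_icc_edges <- function(group_mean_fc, percentile = 98) {
  if (!is.list(group_mean_fc)) group_mean_fc <- list(group_mean_fc)
  dims <- vapply(group_mean_fc, nrow, numeric(1))
  stopifnot(length(unique(dims)) == 1)
  sets <- lapply(group_mean_fc, function(m) {
    w <- abs(upper_tri_vec(as.matrix(m)))
    which(w >= quantile(w, percentile / 100))
  })
  sort(Reduce(intersect, sets))
}

#' Upper-triangle edge index table
#'
#' @param p Node count.
#' @return Tibble mapping `edge` (column-major upper-triangle position) to
#'   node pair `(i, j)`, `i < j`.
#' @export
upper_tri_index_table <- function(p) upper_tri_index(p)

#' Similarity of FC to a reference connectivity matrix
#'
#' Pearson correlation over the strict upper triangle between an FC matrix
#' (individual or group-averaged) and a reference: a simulated ground-truth
#' weight matrix or a structural connectivity matrix.  A directed reference
#' is symmetrized as `(W + t(W)) / 2` first; all edges are included
#' regardless of zeros in either matrix.
#'
#' @param fc Square FC matrix.
#' @param target Square reference matrix, or an [fc_network] (its weight
#'   matrix is used).
#' @return Pearson r.
#' @export
target_similarity <- function(fc, target) {
  if (inherits(target, "fc_network")) target <- target$weights
  target <- as.matrix(target)
  stopifnot(all(dim(fc) == dim(target)))
  if (!isSymmetric(unname(target))) target <- symmetrize(target)
  cor(upper_tri_vec(as.matrix(fc)), upper_tri_vec(target))
}

#' Threshold an FC matrix to a target edge density
#'
#' Keeps the `floor(target_density * n_edges)` upper-triangle edges with
#' the largest absolute weights (ties broken by edge index) and zeroes the
#' rest; to avoid a gap between zero and the surviving weights, the
#' minimum surviving magnitude is subtracted from every surviving
#' magnitude, preserving sign.  Used to compare dense FC estimates against
#' sparse structural references on equal footing.
#'
#' @param fc An [fc_matrix] or square symmetric matrix.
#' @param target_density Proportion of edges to retain, in (0, 1].
#' @return An [fc_matrix] with thresholded weights.
#' @export
density_threshold <- function(fc, target_density) {
  stopifnot(target_density > 0, target_density <= 1)
  if (target_density == 1) return(fc)  # nothing removed, no gap to close
  m <- as.matrix(fc)
  w <- upper_tri_vec(m)
  n_keep <- floor(target_density * length(w))
  keep <- head(order(-abs(w), seq_along(w)), n_keep)
  out <- numeric(length(w))
  if (n_keep > 0) {
    minmag <- min(abs(w[keep]))
    out[keep] <- sign(w[keep]) * (abs(w[keep]) - minmag)
  }
  res <- matrix(0, nrow(m), ncol(m))
  res[upper.tri(res)] <- out
  res <- res + t(res)
  fc_matrix(res, method = attr(fc, "method") %||% "thresholded",
            hyperparameter = attr(fc, "hyperparameter"),
            diagnostics = list(target_density = target_density,
                               n_kept = n_keep))
}

#' Motion-confound sensitivity of FC edges (QC-FC)
#'
#' For every edge, the partial Pearson correlation across subjects between
#' edge weight and mean head motion (relative RMS displacement),
#' conditioned on subject age and sex, with Benjamini-Hochberg FDR
#' correction across edges.  Optionally restricts each edge's computation
#' to subjects with non-negligible weights (`|w| > w_thresh`), skipping
#' edges retaining fewer than `min_prop` of subjects, which removes the
#' advantage sparse methods would otherwise get from structurally zero
#' edges.
#'
#' @param cohort An [fc_cohort][generate_cohort], or a list with elements
#'   `fc` (list of per-subject FC matrices) and `covariates` (data frame
#'   with `motion`, `age`, `sex` columns).
#' @param nonzero_control Apply the nonzero-edge control?
#' @param w_thresh,min_prop Nonzero-edge control parameters.
#' @param alpha Significance level applied to FDR-adjusted p-values.
#' @return An `fc_qcfc` object: tibble of per-edge results (`edge`, `i`,
#'   `j`, `r`, `p`, `p_adj`, `n_used`) with summary statistics available
#'   via [glance()].
#' @export
qcfc <- function(cohort, nonzero_control = FALSE, w_thresh = 0.01,
                 min_prop = 0.8, alpha = 0.05) {
  fc <- cohort$fc
  cov <- cohort$covariates
  stopifnot(!is.null(fc), !is.null(cov),
            all(c("motion", "age", "sex") %in% names(cov)))
  n <- length(fc)
  if (n < 10) stop("QC-FC needs at least 10 subjects", call. = FALSE)
  w <- do.call(rbind, lapply(fc, upper_tri_vec))
  z <- cbind(1, cov$age, as.numeric(cov$sex))
  df <- n - 2 - 2  # two conditioning covariates
  p_nodes <- nrow(fc[[1]])
  idx <- upper_tri_index(p_nodes)

  if (!nonzero_control) {
    r <- partial_cor_columns(w, cov$motion, z)
    n_used <- rep(n, ncol(w))
  } else {
    r <- rep(NA_real_, ncol(w))
    n_used <- rep(NA_integer_, ncol(w))
    for (e in seq_len(ncol(w))) {
      keep <- abs(w[, e]) > w_thresh
      if (mean(keep) < min_prop) next
      n_used[e] <- sum(keep)
      r[e] <- partial_cor_columns(w[keep, e, drop = FALSE],
                                  cov$motion[keep], z[keep, , drop = FALSE])
    }
    df <- n_used - 2 - 2
  }
  tval <- r * sqrt(pmax(df, 1) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tval), pmax(df, 1))
  tested <- !is.na(r)
  p_adj <- rep(NA_real_, length(r))
  p_adj[tested] <- p.adjust(pval[tested], method = "BH")
  out <- dplyr::mutate(idx, r = r, p = pval, p_adj = p_adj, n_used = n_used)
  structure(list(
    edges = out,
    prop_significant = mean(p_adj[tested] < alpha),
    median_abs_qcfc = stats::median(abs(r[tested])),
    n_edges_tested = sum(tested), alpha = alpha,
    nonzero_control = nonzero_control), class = "fc_qcfc")
}

# Partial correlation of each column of `w` with `v`, conditioning on the
# design matrix `z` (residualize-then-correlate).
partial_cor_columns <- function(w, v, z) {
  qz <- qr(z)
  rw <- qr.resid(qz, w)
  rv <- qr.resid(qz, v)
  as.vector(cor(rw, rv))
}

#' @export
print.fc_qcfc <- function(x, ...) {
  cat(sprintf(
    "<fc_qcfc> %d edges tested: %.2f%% significant (BH alpha %.2g), median |QC-FC| = %.3f\n",
    x$n_edges_tested, 100 * x$prop_significant, x$alpha, x$median_abs_qcfc))
  invisible(x)
}

#' Dependent-sample t-test on Fisher-z transformed correlations
#'
#' The paired comparison used throughout the benchmark tables: two matched
#' vectors of Pearson correlations are Fisher-z transformed (`atanh`),
#' compared with a two-tailed dependent-sample t-test, and the mean
#' difference is transformed back to a correlation-scale `mean_dr`.
#'
#' @param r_a,r_b Matched vectors of Pearson correlations.
#' @return One-row tibble: `mean_dr`, `t`, `df`, `p`.
#' @export
compare_dependent_correlations <- function(r_a, r_b) {
  stopifnot(length(r_a) == length(r_b), length(r_a) >= 2)
  d <- atanh(r_a) - atanh(r_b)
  n <- length(d)
  tstat <- if (sd(d) == 0 && mean(d) == 0) 0 else
    mean(d) / (sd(d) / sqrt(n))
  tibble::tibble(mean_dr = tanh(mean(d)), t = tstat, df = n - 1,
                 p = 2 * pt(-abs(tstat), n - 1))
}

#' Test for a difference between correlated correlations
#'
#' Meng, Rosenthal and Rubin's z-test comparing two Pearson correlations
#' `r_a = cor(x, y_a)` and `r_b = cor(x, y_b)` that share the variable `x`,
#' given the correlation `r_ab = cor(y_a, y_b)` between the non-shared
#' variables and the common sample size.  Used to compare the pooled
#' prediction accuracies of two FC methods against the same observed
#' outcome.
#'
#' @param r_a,r_b The two correlations sharing a variable.
#' @param r_ab Correlation between the two non-shared variables.
#' @param n Sample size.
#' @return One-row tibble: `z`, `p` (two-tailed).
#' @export
meng_correlated_correlations <- function(r_a, r_b, r_ab, n) {
  stopifnot(n > 3, abs(r_a) < 1, abs(r_b) < 1, abs(r_ab) <= 1)
  rbar2 <- (r_a^2 + r_b^2) / 2
  f <- min((1 - r_ab) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r_a) - atanh(r_b)) * sqrt((n - 3) / (2 * (1 - r_ab) * h))
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Pairwise method comparison table
#'
#' Applies [compare_dependent_correlations()] to every pair of methods in a
#' per-entity correlation table, recording the Bonferroni-adjusted alpha
#' for the family of comparisons.
#'
#' @param values Tibble with columns `entity`, `method`, `value` (Pearson
#'   r per network/subject and method).
#' @param alpha Family-wise error rate before Bonferroni division.
#' @return Tibble of pairwise comparisons with `mean_dr`, `t`, `df`, `p`,
#'   `alpha_adjusted`, `n_comparisons`, `significant`.
#' @export
compare_methods_table <- function(values, alpha = 0.05) {
  stopifnot(all(c("entity", "method", "value") %in% names(values)))
  wide <- tidyr::pivot_wider(values, id_cols = "entity",
                             names_from = "method", values_from = "value")
  methods <- setdiff(names(wide), "entity")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  alpha_adj <- alpha / length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    res <- compare_dependent_correlations(wide[[pr[1]]], wide[[pr[2]]])
    dplyr::mutate(res, method_a = pr[1], method_b = pr[2],
                  alpha_adjusted = alpha_adj,
                  n_comparisons = length(pairs),
                  significant = res$p < alpha_adj,
                  .before = 1)
  })
}
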