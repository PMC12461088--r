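test_that("between-session similarity behaves on identical and negated inputs", {
  set.seed(70)
  m <- fc_matrix(matrix(rnorm(100), 10, 10), method = "pairwise")
  expect_equal(between_session_similarity(m, m), 1)
  neg <- fc_matrix(-as.matrix(m), method = "pairwise")
  expect_equal(between_session_similarity(m, neg), -1)
})

test_that("ICC(1,1) matches a one-way ANOVA oracle", {
  tab <- matrix(c(9, 6, 8, 7, 8, 2,
                  7, 2, 4, 1, 6, 2), 6, 2)
  expect_equal(icc_1_1(tab), aov_icc(tab), tolerance = 1e-12)
  # identical sessions within subjects, subjects differ: ICC = 1
  same <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(icc_1_1(same), 1)
  # pure noise: per-edge ICCs center on zero
  set.seed(71)
  n_sub <- 25
  fcs1 <- replicate(n_sub, fc_matrix(matrix(rnorm(400), 20, 20), "x"),
                    simplify = FALSE)
  fcs2 <- replicate(n_sub, fc_matrix(matrix(rnorm(400), 20, 20), "x"),
                    simplify = FALSE)
  icc <- icc_per_edge(fcs1, fcs2)
  expect_lt(abs(mean(icc$icc)), 0.05)
  # vectorized version agrees with the scalar definition edge by edge
  e1 <- vapply(fcs1, function(m) m[1, 2], numeric(1))
  e2 <- vapply(fcs2, function(m) m[1, 2], numeric(1))
  expect_equal(icc$icc[1], icc_1_1(cbind(e1, e2)), tolerance = 1e-12)
})

test_that("strong-edge intersection selects the top percentile per method", {
  set.seed(72)
  a <- fc_matrix(matrix(rnorm(100 * 100), 100, 100), "a")
  edges <- select_icc_edges(list(a), percentile = 98)
  expect_true(length(edges) %in% c(99, 100))  # ~2% of 4950 edges
  # disjoint top sets intersect to nothing
  m1 <- matrix(0, 10, 10); m1[1, 2] <- 5
  m2 <- matrix(0, 10, 10); m2[3, 4] <- 5
  expect_length(select_icc_edges(list(fc_matrix(m1, "a"),
                                      fc_matrix(m2, "b")),
                                 percentile = 98), 0)
  # shared planted structure is recovered by every method
  base <- matrix(0, 10, 10)
  base[upper.tri(base)][c(3, 17, 30)] <- 10
  base <- base + t(base)
  noisy <- lapply(1:3, function(i) {
    set.seed(80 + i)
    fc_matrix(base + matrix(rnorm(100, sd = 0.1), 10, 10), "m")
  })
  got <- select_icc_edges(noisy, percentile = 94)
  expect_true(all(c(3, 17, 30) %in% got))
})

test_that("target similarity symmetrizes and attenuates with noise", {
  net <- tiny_net(seed = 41)
  truth <- net$weights
  sym <- (truth + t(truth)) / 2
  expect_equal(target_similarity(fc_matrix(sym, "x"), truth), 1)
  # additive noise shrinks r by 1 / sqrt(1 + var_noise / var_signal)
  set.seed(42)
  w <- fcbench:::upper_tri_vec(sym)
  sd_n <- 2 * sd(w)
  reps <- vapply(1:50, function(i) {
    noisy <- sym + matrix(rnorm(400, sd = sd_n), 20, 20)
    target_similarity(fc_matrix(noisy, "x"), truth)
  }, numeric(1))
  # noise enters through the symmetrized upper triangle: averaging the two
  # directions halves its variance
  expected <- 1 / sqrt(1 + (sd_n^2 / 2) / var(w))
  expect_equal(mean(reps), expected, tolerance = 0.05)
})

test_that("density thresholding keeps the exact edge budget and closes the gap", {
  set.seed(43)
  fc <- fc_matrix(matrix(rnorm(100 * 100), 100, 100), "x")
  thr <- density_threshold(fc, 0.1)
  kept <- attr(thr, "diagnostics")$n_kept
  expect_equal(kept, floor(0.1 * 4950))
  w <- fcbench:::upper_tri_vec(as.matrix(thr))
  expect_equal(sum(w != 0), kept - 1)  # the minimum survivor became 0
  expect_equal(min(abs(w[order(-abs(fcbench:::upper_tri_vec(
    as.matrix(fc))))[seq_len(kept)]])), 0)
  # signs preserved on survivors
  orig <- fcbench:::upper_tri_vec(as.matrix(fc))
  nz <- which(w != 0)
  expect_true(all(sign(w[nz]) == sign(orig[nz])))
  # full density: unchanged
  expect_equal(as.matrix(density_threshold(fc, 1)), as.matrix(fc))
})

test_that("QC-FC matches a residualize-then-correlate oracle and recovers planted effects", {
  net <- tiny_net(seed = 44)
  null_coh <- generate_cohort(net, 40, planted_effects(), n_timepoints = 60,
                              seed = 45)
  res <- qcfc(null_coh)
  # oracle check on a handful of edges
  cov <- null_coh$covariates
  w <- do.call(rbind, lapply(null_coh$fc, fcbench:::upper_tri_vec))
  for (e in c(1, 50, 120)) {
    rw <- stats::resid(stats::lm(w[, e] ~ cov$age + cov$sex))
    rm_ <- stats::resid(stats::lm(cov$motion ~ cov$age + cov$sex))
    expect_equal(res$edges$r[e], cor(rw, rm_), tolerance = 1e-10)
  }
  expect_lt(res$prop_significant, 0.05)

  # planted motion effect on 10% of edges dominates the significant set
  n_edges <- 20 * 19 / 2
  eff <- generate_cohort(net, 60,
                         planted_effects(n_motion_edges = round(0.1 * n_edges),
                                         motion_beta = 0.6),
                         n_timepoints = 60, seed = 46)
  hits <- qcfc(eff)
  sig <- hits$edges$edge[!is.na(hits$edges$p_adj) & hits$edges$p_adj < 0.05]
  expect_gt(length(sig), 0)
  expect_gt(mean(sig %in% eff$planted$motion_edges), 0.8)
  recovered <- mean(eff$planted$motion_edges %in% sig)
  expect_gt(recovered, 0.5)

  # nonzero-edge control drops near-zero edges from the family
  ctl <- qcfc(eff, nonzero_control = TRUE)
  expect_lte(ctl$n_edges_tested, n_edges)
})

test_that("dependent-correlation comparison matches the paired t oracle", {
  expect_equal(compare_dependent_correlations(c(0.5, 0.6, 0.7),
                                              c(0.5, 0.6, 0.7)),
               tibble::tibble(mean_dr = 0, t = 0, df = 2, p = 1))
  set.seed(47)
  ra <- runif(20, 0.2, 0.8)
  rb <- pmin(ra + rnorm(20, 0.05, 0.03), 0.95)
  got <- compare_dependent_correlations(ra, rb)
  ref <- stats::t.test(atanh(ra), atanh(rb), paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$df, 19)
  expect_equal(got$mean_dr, tanh(mean(atanh(ra) - atanh(rb))))
  expect_equal(compare_dependent_correlations(c(0.1, 0.5), c(0.2, 0.4))$df, 1)
})

test_that("correlated-correlations z test reproduces the reference formula", {
  expect_equal(meng_correlated_correlations(0.4, 0.4, 0.3, 50)$z, 0)
  # step-by-step arithmetic from the published definition
  r_a <- 0.739; r_b <- 0.512; r_ab <- 0.6; n <- 236
  rbar2 <- (r_a^2 + r_b^2) / 2
  f <- min((1 - r_ab) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z_ref <- (atanh(r_a) - atanh(r_b)) * sqrt((n - 3) / (2 * (1 - r_ab) * h))
  got <- meng_correlated_correlations(r_a, r_b, r_ab, n)
  expect_equal(got$z, z_ref, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(z_ref)), tolerance = 1e-12)
  # two-tailed p symmetric in the sign of z
  flip <- meng_correlated_correlations(r_b, r_a, r_ab, n)
  expect_equal(flip$z, -got$z)
  expect_equal(flip$p, got$p)
})

test_that("Fisher z round-trips and comparison tables carry Bonferroni bookkeeping", {
  r <- c(-0.999, -0.5, 0, 0.3, 0.999)
  expect_equal(tanh(atanh(r)), r, tolerance = 1e-15)
  set.seed(48)
  values <- tidyr::expand_grid(entity = 1:8,
                               method = c("a", "b", "c", "d", "e"))
  values$value <- runif(nrow(values), 0.1, 0.9)
  tab <- compare_methods_table(values)
  expect_equal(nrow(tab), 10)
  expect_equal(unique(tab$alpha_adjusted), 0.005)
  expect_equal(unique(tab$n_comparisons), 10)
})

test_that("metrics are invariant to consistent node relabeling", {
  net <- tiny_net(seed = 49)
  s1 <- simulate_session(net, 120, 0.5, seed = 50)
  s2 <- simulate_session(net, 120, 0.5, seed = 51)
  a <- as.matrix(fc_pairwise(s1))
  b <- as.matrix(fc_pairwise(s2))
  truth <- fcbench:::symmetrize(net$weights)
  set.seed(52)
  perm <- sample(20)
  expect_equal(between_session_similarity(a[perm, perm], b[perm, perm]),
               between_session_similarity(a, b), tolerance = 1e-12)
  expect_equal(target_similarity(a[perm, perm], truth[perm, perm]),
               target_similarity(a, truth), tolerance = 1e-12)
})
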