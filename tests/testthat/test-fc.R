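test_that("z-scoring uses the population-SD convention and is idempotent", {
  x <- matrix(c(1, 2, 3, 5, 5, 8), 3, 2)
  z <- zscore_session(x)
  expect_equal(z[, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(zscore_session(z), z, tolerance = 1e-12)
  expect_equal(colMeans(z), c(0, 0))
  expect_equal(colSums(z^2) / nrow(z), c(1, 1))
  bad <- cbind(x, 7)
  expect_error(zscore_session(bad), "node 3")
})

test_that("pairwise correlation matches a covariance-formula oracle", {
  x <- matrix(c(1, 2, 4, 3, 0, 1, 1, 2, 5, 4, 4, 9), 4, 3)
  fc <- fc_pairwise(x)
  manual <- function(a, b) {
    mean((a - mean(a)) * (b - mean(b))) /
      sqrt(mean((a - mean(a))^2) * mean((b - mean(b))^2))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(fc[i, j], manual(x[, i], x[, j]), tolerance = 1e-12)
  }
  expect_equal(diag(fc), rep(0, 3))
  dup <- cbind(x, x[, 1], -x[, 1])
  fcd <- fc_pairwise(dup)
  expect_equal(fcd[1, 4], 1)
  expect_equal(fcd[1, 5], -1)
})

test_that("partial correlation separates chains and matches residualization", {
  # chain 1 -> 2 -> 3: conditioning on the middle node removes the 1-3 edge
  w <- matrix(0, 3, 3)
  w[2, 1] <- 0.7
  w[3, 2] <- 0.7
  s <- simulate_session(manual_net(w), 40000, noise_level = 0, seed = 5)
  fc <- fc_partial(s)
  expect_lt(abs(fc[1, 3]), 0.03)
  expect_gt(fc[1, 2], 0.3)
  expect_gt(fc[2, 3], 0.3)
  # marginally nodes 1 and 3 are correlated: pairwise keeps the confound
  expect_gt(fc_pairwise(s)[1, 3], 0.2)

  # equivalence with regress-residuals-and-correlate on a 5-node fixture
  set.seed(8)
  sigma <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  x <- gaussian_session(60, sigma, seed = 9)
  expect_lt(max(abs(as.matrix(fc_partial(x)) - residualization_parcor(x))),
            1e-8)

  # independent white noise: everything near zero
  set.seed(10)
  wn <- matrix(rnorm(5000 * 8), 5000, 8)
  expect_lt(max(abs(fc_partial(wn))), 0.06)
})

test_that("partial correlation refuses underdetermined data", {
  set.seed(1)
  x <- matrix(rnorm(20 * 25), 20, 25)
  expect_error(fc_partial(x), "insufficient data")
  expect_error(fc_partial(matrix(rnorm(25 * 25), 25, 25)),
               "insufficient data")
})

test_that("graphical lasso agrees with an independent ADMM solver", {
  set.seed(11)
  sigma <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  x <- gaussian_session(80, sigma, seed = 12)
  s <- cor(x)
  for (lam in c(0.02, 0.1, 0.3)) {
    fit <- fcbench:::glasso_path_cpp(s, lam, 1e-7, 10000L, 1000L)
    oracle <- admm_glasso(s, lam)
    expect_lt(max(abs(fit$precision[, , 1] - oracle)), 1e-4)
  }
})

test_that("graphical lasso limits: zero penalty and full shrinkage", {
  net <- tiny_net(seed = 5)
  s <- simulate_session(net, 800, 0.5, seed = 6)
  expect_lt(max(abs(as.matrix(fc_glasso(s, 0)) -
                    as.matrix(fc_partial(s)))), 1e-4)
  hard <- fc_glasso(s, 5)
  expect_true(all(hard[upper.tri(hard)] == 0))
  # sparsity is nonincreasing in lambda
  nnz <- vapply(seq(0.01, 0.28, by = 0.03), function(l) {
    sum(as.matrix(fc_glasso(s, l)) != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("graphical ridge matches a quasi-Newton solution of its objective", {
  set.seed(13)
  sigma <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  x <- gaussian_session(70, sigma, seed = 14)
  s <- cor(x)
  for (lam in c(0.2, 0.8)) {
    fit <- fcbench:::gridge_path_cpp(s, lam, 1e-9, 10000L)
    oracle <- bfgs_gridge(s, lam)
    expect_lt(max(abs(fit$precision[, , 1] - oracle)), 1e-4)
  }
})

test_that("graphical ridge limits: zero penalty and monotone shrinkage", {
  net <- tiny_net(seed = 7)
  s <- simulate_session(net, 800, 0.5, seed = 8)
  expect_lt(max(abs(as.matrix(fc_gridge(s, 0)) -
                    as.matrix(fc_partial(s)))), 1e-4)
  mags <- vapply(c(0.2, 0.6, 1.5, 4), function(l) {
    mean(abs(as.matrix(fc_gridge(s, l))))
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
  # dense: no exact zeros expected
  g <- as.matrix(fc_gridge(s, 1))
  expect_true(all(g[upper.tri(g)] != 0))
})

test_that("PC regression matches a step-by-step PCA-then-regress oracle", {
  set.seed(15)
  sigma <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
  x <- gaussian_session(90, sigma, seed = 16)
  for (k in c(2, 4)) {
    expect_lt(max(abs(as.matrix(fc_pcreg(x, k)) - stepwise_pcreg(x, k))),
              1e-8)
  }
  # forced symmetrization is exact
  fc <- fc_pcreg(x, 3)
  expect_identical(as.matrix(fc) - t(as.matrix(fc)), matrix(0, 6, 6))
})

test_that("PC regression with all components reduces to multiple regression", {
  set.seed(17)
  sigma <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  x <- zscore_session(gaussian_session(400, sigma, seed = 18))
  full <- matrix(0, 5, 5)
  for (j in 1:5) {
    full[j, -j] <- stats::coef(stats::lm(x[, j] ~ x[, -j]))[-1]
  }
  expect_lt(max(abs(as.matrix(fc_pcreg(x, 4)) - (full + t(full)) / 2)),
            1e-6)
  expect_error(fc_pcreg(x, 5), "n_components")
})

test_that("all estimators return symmetric, zero-diagonal, bounded matrices", {
  net <- tiny_net(seed = 9)
  s <- simulate_session(net, 300, 0.5, seed = 10)
  fits <- list(fc_pairwise(s), fc_partial(s), fc_glasso(s, 0.05),
               fc_gridge(s, 0.5), fc_pcreg(s, 8))
  for (fc in fits) {
    m <- as.matrix(fc)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
  }
  for (fc in fits[1:2]) {
    expect_true(all(abs(as.matrix(fc)) <= 1))
  }
})

test_that("estimation commutes with node permutation", {
  net <- tiny_net(seed = 11)
  s <- simulate_session(net, 300, 0.5, seed = 12)
  x <- s$data
  set.seed(20)
  perm <- sample(ncol(x))
  for (est in list(
    function(d) as.matrix(fc_pairwise(d)),
    function(d) as.matrix(fc_partial(d)),
    function(d) as.matrix(fc_glasso(d, 0.08)),
    function(d) as.matrix(fc_gridge(d, 0.8)),
    function(d) as.matrix(fc_pcreg(d, 6)))) {
    direct <- est(x[, perm])
    permuted <- est(x)[perm, perm]
    expect_lt(max(abs(direct - permuted)), 1e-4)
  }
})

test_that("partial correlation recovers the population conditional-independence support", {
  # The precision matrix of the linear model X = (I-W)^-1 E is
  # (I-W)'(I-W): its support is the structural skeleton PLUS moralized
  # co-parent pairs, so the recovery target is the population partial
  # correlation support, not the raw edge list.  Edges in the ambiguity
  # band (population |parcor| between 0.02 and 0.06, at the sampling
  # noise floor for this T) are excluded from the comparison.
  net <- tiny_net(seed = 13)
  p <- net$meta$p
  iw <- diag(p) - net$weights
  pop <- -stats::cov2cor(t(iw) %*% iw)
  diag(pop) <- 0
  ppv <- abs(fcbench:::upper_tri_vec(pop))
  strong <- which(ppv >= 0.06)
  unambiguous <- which(ppv >= 0.06 | ppv <= 0.02)
  s <- simulate_session(net, 100 * p, noise_level = 0, seed = 14)
  fcv <- abs(fcbench:::upper_tri_vec(as.matrix(fc_partial(s))))
  est_set <- unambiguous[order(-fcv[unambiguous])][seq_along(strong)]
  jaccard <- length(intersect(est_set, strong)) /
    length(union(est_set, strong))
  expect_gt(jaccard, 0.9)
  # and the sample estimate tracks the population values themselves
  expect_gt(cor(fcv, ppv), 0.95)
})

test_that("estimate_fc dispatches and honors param = 'auto'", {
  net <- tiny_net(seed = 15)
  s <- simulate_session(net, 200, 0.5, seed = 16)
  expect_equal(as.matrix(estimate_fc(s, "pairwise")),
               as.matrix(fc_pairwise(s)))
  auto <- estimate_fc(s, "glasso", param = "auto")
  expect_true(attr(auto, "hyperparameter") > 0)
})
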