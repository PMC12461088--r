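test_that("default networks have the exact modular edge counts", {
  for (seed in c(1L, 77L, 4242L)) {
    net <- generate_network(seed = seed)
    expect_equal(net$meta$n_intra_directed, 700)
    expect_equal(net$meta$n_extra_directed, 186)
    w <- net$weights
    expect_true(all(diag(w) == 0))
    expect_true(all((w != 0) == t(w != 0)))  # bidirectional skeleton
    expect_lt(net$meta$spectral_radius, 1)
    # intra-modular density 700 / (5 * 20 * 19) = 36.84%
    expect_equal(700 / (5 * 20 * 19), 0.3684, tolerance = 1e-4)
    # the two directions carry different weights
    nz <- w != 0
    expect_gt(sum(w[nz] != t(w)[nz]), 0)
  }
})

test_that("degenerate and dense growth configurations count correctly", {
  # seed clique only, no growth steps: complete 4-node skeleton
  clique <- generate_network(p = 4, n_modules = 1, module_size = 4,
                             seed_size = 4, growth_edges = 3,
                             extra_modular_edges = 0, seed = 3)
  expect_equal(sum(clique$weights != 0), 12)
  # doubled-density variant: per module C(8,2) + 12 * 8 = 124 undirected
  # edges, 1240 directed across 5 modules
  dense <- generate_network(seed_size = 8, growth_edges = 8, scale = 0.65,
                            extra_modular_edges = 310, seed = 5)
  expect_equal(dense$meta$n_intra_directed, 1240)
  expect_equal(dense$meta$n_extra_directed, 310)
  expect_lt(dense$meta$spectral_radius, 1)
})

test_that("preferential attachment samples nodes proportionally to degree", {
  deg <- c(8, 4, 2, 1, 1)
  set.seed(99)
  draws <- replicate(20000, fcbench:::preferential_sample(1:5, 1, deg))
  obs <- tabulate(draws, 5)
  chi <- suppressWarnings(chisq.test(obs, p = deg / sum(deg)))
  expect_gt(chi$p.value, 1e-3)
  # without-replacement draws never repeat a node
  multi <- replicate(200, fcbench:::preferential_sample(1:5, 3, deg))
  expect_true(all(apply(multi, 2, anyDuplicated) == 0))
  # rich-get-richer: module seed nodes end with higher degree than late ones
  net <- generate_network(seed = 11)
  deg_all <- colSums(net$weights != 0)
  seeds <- as.vector(outer(1:4, seq(0, 80, by = 20), "+"))
  late <- as.vector(outer(17:20, seq(0, 80, by = 20), "+"))
  expect_gt(mean(deg_all[seeds]), mean(deg_all[late]))
})

test_that("impossible parameter combinations fail loudly", {
  expect_error(generate_network(extra_modular_edges = 187, seed = 1),
               "even")
  expect_error(generate_network(p = 10, n_modules = 2, module_size = 5,
                                seed_size = 3, growth_edges = 2,
                                extra_modular_edges = 60, seed = 1),
               "exceeds")
  expect_error(generate_network(p = 10, seed = 1))  # p != modules * size
})

test_that("sessions realize the linear structural model", {
  # W = 0: activities are exactly the intrinsic noise draws
  net0 <- tiny_net(seed = 2)
  net0$weights[] <- 0
  s <- simulate_session(net0, 50, noise_level = 0, seed = 9)
  set.seed(9)
  e <- matrix(rnorm(50 * 20), 50, 20)
  expect_equal(s$data, e)

  # 2-node analytic correlation from Sigma = (I-W)^-1 (I-W)^-T
  w <- matrix(c(0, 0, 0.6, 0), 2, 2)  # node 1 drives node 2
  m <- solve(diag(2) - w)
  sigma <- m %*% t(m)
  rho <- sigma[1, 2] / sqrt(sigma[1, 1] * sigma[2, 2])
  s2 <- simulate_session(manual_net(w), 200000, noise_level = 0, seed = 4)
  expect_equal(cor(s2$data)[1, 2], rho, tolerance = 0.01)

  # 10-node covariance convergence in Frobenius norm
  net10 <- generate_network(p = 10, n_modules = 2, module_size = 5,
                            seed_size = 3, growth_edges = 2,
                            extra_modular_edges = 4, seed = 6)
  m10 <- solve(diag(10) - net10$weights)
  sigma10 <- m10 %*% t(m10)
  s10 <- simulate_session(net10, 1e5, noise_level = 0, seed = 8)
  emp <- crossprod(s10$data) / nrow(s10$data)
  expect_lt(norm(emp - sigma10, "F") / norm(sigma10, "F"), 0.05)
})

test_that("measurement noise is scaled to each node's signal SD", {
  net <- tiny_net(seed = 3)
  clean <- simulate_session(net, 4000, noise_level = 0, seed = 21)
  noisy <- simulate_session(net, 4000, noise_level = 0.5, seed = 21)
  added <- noisy$data - clean$data   # same seed: identical intrinsic draws
  ratio <- apply(added, 2, var) / apply(clean$data, 2, var)
  expect_equal(mean(ratio), 0.25, tolerance = 0.02)
})

test_that("haemodynamic sessions have renewal statistics and length", {
  net <- manual_net(matrix(0, 3, 3))
  s <- simulate_hrf_session(net, duration_s = 1500, noise_level = 0,
                            neural_noise_frac = 0, seed = 12)
  expect_equal(nrow(s$data), floor(1500 / 2))
  expect_equal(s$tr, 2)

  # stationary up-state occupancy 2.5 / (2.5 + 10) = 0.2
  set.seed(31)
  train <- fcbench:::binary_state_train(200000, 0.05, 2.5, 10)
  # discretizing holding times to 50 ms steps biases occupancy up slightly
  expect_lt(abs(mean(train) - 0.2), 0.02)

  # with zero mixing and no noise the output is exactly the HRF-convolved,
  # downsampled state trains
  set.seed(12)
  states <- vapply(1:3, function(i) {
    fcbench:::binary_state_train(round(1500 / 0.05), 0.05, 2.5, 10)
  }, numeric(round(1500 / 0.05)))
  h <- fcbench:::canonical_hrf(0.05)
  conv <- apply(states, 2, function(col) {
    stats::convolve(col, rev(h), type = "open")[seq_len(nrow(states))]
  })
  manual <- conv[(seq_len(750) - 1) * 40 + 1, ]
  expect_equal(s$data, manual)
})

test_that("cohorts plant recoverable outcome structure and round-trip", {
  net <- tiny_net(seed = 4)
  coh <- generate_cohort(net, n_subjects = 60,
                         planted = planted_effects(n_outcome_edges = 20,
                                                   outcome_noise_sd = 0.5),
                         n_timepoints = 80, seed = 13)
  expect_equal(nrow(coh$covariates), 60)
  expect_length(coh$fc, 60)
  # attenuation: cor(signal + noise, signal) = 1 / sqrt(1 + sd^2)
  expect_equal(cor(coh$covariates$outcome, coh$planted$outcome_signal),
               1 / sqrt(1.25), tolerance = 0.08)

  tiny <- generate_cohort(net, n_subjects = 3, n_timepoints = 40, seed = 14)
  dir <- file.path(tempdir(), "cohort-roundtrip")
  write_cohort(tiny, dir)
  back <- read_cohort(dir)
  expect_equal(back$covariates$motion, tiny$covariates$motion)
  for (i in 1:3) {
    expect_equal(as.matrix(back$fc[[i]]), as.matrix(tiny$fc[[i]]),
                 tolerance = 1e-12)
  }
  unlink(dir, recursive = TRUE)
})
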