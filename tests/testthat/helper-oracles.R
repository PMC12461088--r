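# Independent oracles.  These deliberately use different algorithms from
# the package implementations so agreement is evidence of correctness,
# not shared code.

# Graphical lasso via ADMM (scaled form).  The package solves the same
# objective by block coordinate descent; ADMM shares nothing with it.
# Objective: tr(S P) - logdet P + lambda * sum_{i != j} |P_ij|.
admm_glasso <- function(s, lambda, rho = 1, iters = 5000, tol = 1e-10) {
  p <- nrow(s)
  z <- diag(p)
  u <- matrix(0, p, p)
  for (it in seq_len(iters)) {
    # x-update: minimize tr(SX) - logdet X + rho/2 ||X - Z + U||^2
    e <- eigen(rho * (z - u) - s, symmetric = TRUE)
    xev <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    x <- e$vectors %*% (xev * t(e$vectors))
    # z-update: soft-threshold off-diagonal entries of X + U
    z_old <- z
    a <- x + u
    z <- sign(a) * pmax(abs(a) - lambda / rho, 0)
    diag(z) <- diag(a)                 # diagonal unpenalized
    u <- u + x - z
    if (max(abs(z - z_old)) < tol && max(abs(x - z)) < tol) break
  }
  z
}

# Ridge-penalized precision via generic quasi-Newton on the smooth
# objective, parameterized by the upper triangle (including diagonal).
bfgs_gridge <- function(s, lambda) {
  p <- nrow(s)
  ut <- upper.tri(diag(p), diag = TRUE)
  unpack <- function(th) {
    m <- matrix(0, p, p)
    m[ut] <- th
    m + t(m) - diag(diag(m))
  }
  obj <- function(th) {
    pm <- unpack(th)
    ev <- eigen(pm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) return(1e10)
    sum(diag(s %*% pm)) - determinant(pm)$modulus[1] +
      lambda * (sum(pm^2) - sum(diag(pm)^2))
  }
  fit <- stats::optim(diag(p)[ut], obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  unpack(fit$par)
}

# Partial correlation by the regress-out-and-correlate construction.
residualization_parcor <- function(x) {
  p <- ncol(x)
  out <- diag(0, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ri <- stats::resid(stats::lm(x[, i] ~ x[, -c(i, j)]))
      rj <- stats::resid(stats::lm(x[, j] ~ x[, -c(i, j)]))
      out[i, j] <- out[j, i] <- cor(ri, rj)
    }
  }
  out
}

# PC regression, spelled out step by step with prcomp() and lm().
stepwise_pcreg <- function(x, k) {
  x <- scale(x) / sqrt((nrow(x) - 1) / nrow(x))  # population-SD z-score
  p <- ncol(x)
  b <- matrix(0, p, p)
  for (j in seq_len(p)) {
    pc <- stats::prcomp(x[, -j], center = TRUE, scale. = FALSE)
    scores <- pc$x[, seq_len(k), drop = FALSE]
    fit <- stats::lm(x[, j] ~ scores)
    b[j, -j] <- pc$rotation[, seq_len(k), drop = FALSE] %*%
      stats::coef(fit)[-1]
  }
  (b + t(b)) / 2
}

# ICC(1,1) through R's own one-way ANOVA machinery.
aov_icc <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))))
  tab <- summary(stats::aov(y ~ subject, data = df))[[1]]
  bms <- tab["subject", "Mean Sq"]
  wms <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (bms - wms) / (bms + (k - 1) * wms)
}

# Population R^2 of predicting node j from the others with coefficient
# vector b_j (row j of B), given the generating covariance.
population_cv_r2 <- function(sigma, b) {
  d <- sqrt(diag(sigma))
  sigma_z <- sigma / tcrossprod(d)   # estimators see z-scored data
  p <- nrow(sigma_z)
  vals <- vapply(seq_len(p), function(j) {
    bj <- b[j, ]
    1 - (sigma_z[j, j] - 2 * sum(bj * sigma_z[, j]) +
           as.numeric(t(bj) %*% sigma_z %*% bj)) / sigma_z[j, j]
  }, numeric(1))
  mean(vals)
}
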