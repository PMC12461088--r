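#' Predict an individual-difference outcome from FC edges
#'
#' Ridge regression of a per-subject outcome on vectorized FC edge weights
#' (strict upper triangle), evaluated with 10-fold cross-validation: for
#' each outer fold the ridge strength is chosen by an inner
#' cross-validation restricted to the training subjects, the model is fit
#' on the training subjects only and applied to the held-out fold, and the
#' predictions pooled over folds are correlated with the actual values.
#' Ridge is essential because the number of edges far exceeds the number
#' of subjects; fits use the kernel (SVD) form so cost scales with
#' subjects, not edges.
#'
#' An optional confound can be residualized from the outcome first.  By
#' default the residualization is itself fitted on the training subjects
#' of each outer fold only (leakage-safe); `confound_global = TRUE`
#' residualizes once on the full sample instead.
#'
#' @param cohort An [fc_cohort][generate_cohort] (or list with `fc` and
#'   `covariates`).
#' @param outcome Name of the outcome column in `cohort$covariates`.
#' @param confound Optional name of a covariate to regress out of the
#'   outcome.
#' @param confound_global Residualize on the full sample rather than per
#'   training fold.
#' @param n_folds Outer folds.
#' @param inner_folds Folds of the inner ridge-strength selection.
#' @param lambda_grid Ridge penalties searched by the inner CV
#'   (logarithmic over 1e-3 to 1e4 by default).
#' @param seed Seed for the outer/inner fold assignment.
#' @return An `fc_prediction`: list with `predicted`, `actual` (pooled,
#'   in subject order), `accuracy` (Pearson r), `fold` assignment and
#'   `lambda_per_fold`.  [tidy()] gives per-subject rows, [glance()] the
#'   summary.
#' @export
predict_outcome <- function(cohort, outcome = "outcome", confound = NULL,
                            confound_global = FALSE, n_folds = 10,
                            inner_folds = 5,
                            lambda_grid = 10^seq(-3, 4, length.out = 15),
                            seed = 1L) {
  cov <- cohort$covariates
  stopifnot(outcome %in% names(cov))
  x <- do.call(rbind, lapply(cohort$fc, upper_tri_vec))
  y <- cov[[outcome]]
  n <- nrow(x)
  if (n < 20) stop("prediction needs at least 20 subjects", call. = FALSE)
  conf <- if (!is.null(confound)) cov[[confound]] else NULL
  if (!is.null(conf) && confound_global) {
    y <- stats::resid(stats::lm(y ~ conf))
    conf <- NULL
  }
  set.seed(child_seed(seed, 0L))
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  predicted <- rep(NA_real_, n)
  actual <- y
  lambda_per_fold <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    ytr <- y[tr]; yte <- y[te]
    if (!is.null(conf)) {
      cf_fit <- stats::lm(ytr ~ conf[tr])
      ytr <- stats::resid(cf_fit)
      yte <- yte - (stats::coef(cf_fit)[1] + stats::coef(cf_fit)[2] * conf[te])
      actual[te] <- yte
    }
    lam <- choose_ridge_lambda(x[tr, , drop = FALSE], ytr, lambda_grid,
                               inner_folds, child_seed(seed, f))
    lambda_per_fold[f] <- lam
    predicted[te] <- ridge_predict(x[tr, , drop = FALSE], ytr,
                                   x[te, , drop = FALSE], lam)
  }
  structure(list(predicted = predicted, actual = actual,
                 accuracy = cor(predicted, actual), fold = fold,
                 lambda_per_fold = lambda_per_fold, outcome = outcome,
                 confound = confound), class = "fc_prediction")
}

# Ridge with intercept via SVD of the centered training matrix; returns
# predictions for all lambdas at once (columns).
ridge_predict_all <- function(xtr, ytr, xte, lambdas) {
  mu <- colMeans(xtr)
  my <- mean(ytr)
  xtr_c <- sweep(xtr, 2, mu)
  xte_c <- sweep(xte, 2, mu)
  sv <- svd(xtr_c, nu = min(dim(xtr)), nv = 0)
  keep <- sv$d > max(sv$d) * 1e-12
  u <- sv$u[, keep, drop = FALSE]
  d <- sv$d[keep]
  uty <- as.vector(crossprod(u, ytr - my))
  # beta(l) = V diag(d / (d^2 + l)) U'yc with V = Xtr_c' U D^-1, so
  # Xte_c beta(l) = (Xte_c Xtr_c' U D^-1) (d / (d^2 + l) * uty)
  zte <- tcrossprod(xte_c, xtr_c) %*% sweep(u, 2, d, "/")
  out <- vapply(lambdas, function(l) {
    as.vector(my + zte %*% (d / (d^2 + l) * uty))
  }, numeric(nrow(xte)))
  matrix(out, nrow = nrow(xte))
}

ridge_predict <- function(xtr, ytr, xte, lambda) {
  ridge_predict_all(xtr, ytr, xte, lambda)[, 1]
}

# Inner CV over the lambda grid; minimizes held-out MSE.
choose_ridge_lambda <- function(x, y, lambdas, inner_folds, seed) {
  n <- nrow(x)
  set.seed(seed)
  fold <- sample(rep(seq_len(inner_folds), length.out = n))
  err <- matrix(0, inner_folds, length(lambdas))
  for (f in seq_len(inner_folds)) {
    te <- which(fold == f); tr <- which(fold != f)
    pred <- ridge_predict_all(x[tr, , drop = FALSE], y[tr],
                              x[te, , drop = FALSE], lambdas)
    err[f, ] <- colMeans((pred - y[te])^2)
  }
  lambdas[which.min(colMeans(err))]
}

#' @export
print.fc_prediction <- function(x, ...) {
  cat(sprintf("<fc_prediction> %s: pooled r = %.3f over %d subjects\n",
              x$outcome, x$accuracy, length(x$predicted)))
  invisible(x)
}
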