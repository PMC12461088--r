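#' Functional connectivity matrix container
#'
#' All five estimators return an `fc_matrix`: a plain numeric p x p matrix
#' with exact symmetry and a zero diagonal, carrying the estimating method,
#' its hyperparameter (if any) and solver diagnostics as attributes.
#'
#' @param values Square numeric matrix.
#' @param method One of `"pairwise"`, `"partial"`, `"glasso"`, `"gridge"`,
#'   `"pcreg"` (or another label for externally supplied matrices).
#' @param hyperparameter Regularization value, or `NULL`.
#' @param source Optional session identifier.
#' @param diagnostics Optional list of solver diagnostics.
#' @return An `fc_matrix`.
#' @export
fc_matrix <- function(values, method, hyperparameter = NULL, source = NULL,
                      diagnostics = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  values <- symmetrize(values)
  diag(values) <- 0
  structure(values, class = c("fc_matrix", "matrix"),
            method = method, hyperparameter = hyperparameter,
            source = source, diagnostics = diagnostics)
}

#' @export
print.fc_matrix <- function(x, ...) {
  h <- attr(x, "hyperparameter")
  cat(sprintf("<fc_matrix> %d x %d, method = %s%s\n", nrow(x), ncol(x),
              attr(x, "method"),
              if (is.null(h)) "" else sprintf(" (hyperparameter %g)", h)))
  invisible(x)
}

fc_values <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}

#' @export
as.matrix.fc_matrix <- function(x, ...) fc_values(x)

#' Z-score a session
#'
#' Standardizes every node's time series to mean 0 and unit variance using
#' the population-SD convention (denominator `T`).  All estimators operate
#' on z-scored data; since correlation is scale-free this only matters for
#' held-out prediction during hyperparameter selection.
#'
#' @param session An `fc_session` or timepoints x nodes matrix.
#' @return The same type of object with standardized columns.
#' @export
zscore_session <- function(session) {
  if (inherits(session, "fc_session")) {
    session$data <- zscore_matrix(session$data)
    session
  } else {
    zscore_matrix(session_data(session))
  }
}

# Sample correlation matrix with constant-column check.
session_cor <- function(session) {
  x <- session_data(session)
  if (nrow(x) < 2) stop("need at least 2 timepoints", call. = FALSE)
  s <- apply(x, 2, sd)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad) > 0) {
    stop(sprintf("constant time series: node %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cor(x)
}

#' Pairwise Pearson correlation FC
#'
#' The field-standard estimator: the Pearson correlation between every pair
#' of nodes' time series, with the (uninformative) unit diagonal set to 0.
#'
#' @inheritParams zscore_session
#' @return An [fc_matrix] with method `"pairwise"`.
#' @export
fc_pairwise <- function(session) {
  x <- session_data(session)
  if (nrow(x) < 3) stop("need at least 3 timepoints", call. = FALSE)
  fc_matrix(session_cor(session), method = "pairwise")
}

#' Unregularized partial correlation FC
#'
#' Inverts the sample correlation matrix to obtain the precision matrix `P`
#' and converts it to partial correlations
#' `r_ij|C = -P_ij / sqrt(P_ii P_jj)`, the correlation between nodes `i`
#' and `j` conditioned on all remaining nodes.  Requires more timepoints
#' than nodes; otherwise the correlation matrix is singular and an
#' "insufficient data" error is raised.
#'
#' @inheritParams zscore_session
#' @return An [fc_matrix] with method `"partial"`.
#' @export
fc_partial <- function(session) {
  x <- session_data(session)
  if (nrow(x) <= ncol(x)) {
    stop(sprintf(paste0("insufficient data: partial correlation requires ",
                        "more timepoints (T = %d) than nodes (p = %d)"),
                 nrow(x), ncol(x)), call. = FALSE)
  }
  r <- session_cor(session)
  prec <- tryCatch(solve(r), error = function(e) {
    stop("insufficient data: sample correlation matrix is singular",
         call. = FALSE)
  })
  fc_matrix(precision_to_parcor(prec), method = "partial")
}

precision_to_parcor <- function(prec) {
  d <- 1 / sqrt(diag(prec))
  pc <- -prec * tcrossprod(d)
  diag(pc) <- 0
  pc
}

#' Graphical lasso FC
#'
#' L1-penalized partial correlation: the precision matrix maximizes the
#' Gaussian log-likelihood minus `lambda1 * sum_(i != j) |P_ij|` (the
#' diagonal is not penalized), estimated by block coordinate descent, then
#' converted to partial correlations.  The L1 penalty drives weak
#' conditional dependencies to exactly zero, giving sparse, reliable
#' estimates that remain usable when `T < p`.
#'
#' @inheritParams zscore_session
#' @param lambda1 Nonnegative L1 penalty weight.
#' @param tol Convergence tolerance (maximum change of the fitted
#'   covariance between sweeps).
#' @param maxit Iteration cap for outer sweeps and inner lasso loops.
#' @return An [fc_matrix] with method `"glasso"`; solver iteration count in
#'   `attr(, "diagnostics")`.
#' @export
fc_glasso <- function(session, lambda1, tol = 1e-5, maxit = 10000L,
                      inner_maxit = 1000L) {
  stopifnot(length(lambda1) == 1, lambda1 >= 0)
  x <- session_data(session)
  if (lambda1 == 0 && nrow(x) <= ncol(x)) {
    stop("insufficient data: lambda1 = 0 requires more timepoints than ",
         "nodes", call. = FALSE)
  }
  s <- session_cor(session)
  fit <- glasso_path_cpp(s, lambda1, tol, as.integer(maxit),
                         as.integer(inner_maxit))
  if (fit$iters[1] >= maxit) {
    stop(sprintf("graphical lasso did not converge in %d sweeps (lambda1 = %g)",
                 maxit, lambda1), call. = FALSE)
  }
  fc_matrix(fit$parcor[, , 1], method = "glasso", hyperparameter = lambda1,
            diagnostics = list(iterations = fit$iters[1], tol = tol))
}

#' Graphical ridge FC
#'
#' L2 (Tikhonov) penalized partial correlation: the precision matrix
#' maximizes the Gaussian log-likelihood minus
#' `lambda2 * sum_(i != j) P_ij^2` (diagonal unpenalized).  The squared
#' penalty shrinks all conditional dependencies toward zero without forcing
#' exact zeros, so the result is dense.  Solved by an MM fixed point whose
#' subproblems have closed-form eigenvalue solutions; the solution is
#' checked in tests against an independent numeric optimizer.
#'
#' @inheritParams fc_glasso
#' @param lambda2 Nonnegative L2 penalty weight.
#' @return An [fc_matrix] with method `"gridge"`.
#' @export
fc_gridge <- function(session, lambda2, tol = 1e-7, maxit = 10000L) {
  stopifnot(length(lambda2) == 1, lambda2 >= 0)
  x <- session_data(session)
  if (lambda2 == 0 && nrow(x) <= ncol(x)) {
    stop("insufficient data: lambda2 = 0 requires more timepoints than ",
         "nodes", call. = FALSE)
  }
  s <- session_cor(session)
  fit <- gridge_path_cpp(s, lambda2, tol, as.integer(maxit))
  fc_matrix(fit$parcor[, , 1], method = "gridge", hyperparameter = lambda2,
            diagnostics = list(iterations = fit$iters[1], tol = tol))
}

#' Principal-component regression FC
#'
#' For every target node, performs PCA on the other `p - 1` (z-scored)
#' time series, regresses the target on the `n_components` highest-variance
#' component scores, and back-projects the component coefficients to
#' per-predictor weights, which fill the target's row of the FC matrix.
#' Using fewer components regularizes the per-node multiple regression.
#' Because row-wise regression is asymmetric, the final matrix is
#' symmetrized by averaging with its transpose.
#'
#' @inheritParams zscore_session
#' @param n_components Number of leading principal components
#'   (`1 <= n_components <= min(p - 1, T)`).
#' @return An [fc_matrix] with method `"pcreg"`.
#' @export
fc_pcreg <- function(session, n_components) {
  x <- zscore_matrix(session_data(session))
  p <- ncol(x)
  k <- as.integer(n_components)
  if (k < 1 || k > p - 1 || k > nrow(x)) {
    stop(sprintf("n_components must be in [1, min(p - 1, T)] = [1, %d]",
                 min(p - 1, nrow(x))), call. = FALSE)
  }
  b <- pcreg_path(x, k)[[1]]
  fc_matrix(b, method = "pcreg", hyperparameter = k)
}

#' Estimate FC with any method
#'
#' Thin dispatcher over the five estimators.  With `param = "auto"` the
#' hyperparameter of a regularized method is first chosen by
#' [select_hyperparameter()].
#'
#' @inheritParams zscore_session
#' @param method Estimator label.
#' @param param Hyperparameter value, `"auto"`, or `NULL` for
#'   unregularized methods.
#' @param ... Passed to the underlying estimator (and to the selector when
#'   `param = "auto"`).
#' @return An [fc_matrix].
#' @export
estimate_fc <- function(session,
                        method = c("pairwise", "partial", "glasso",
                                   "gridge", "pcreg"),
                        param = NULL, ...) {
  method <- match.arg(method)
  if (identical(param, "auto")) {
    if (method %in% c("pairwise", "partial")) {
      param <- NULL
    } else {
      param <- select_hyperparameter(session, method)$best_value
    }
  }
  switch(method,
         pairwise = fc_pairwise(session),
         partial = fc_partial(session),
         glasso = fc_glasso(session, lambda1 = param, ...),
         gridge = fc_gridge(session, lambda2 = param, ...),
         pcreg = fc_pcreg(session, n_components = param, ...))
}
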