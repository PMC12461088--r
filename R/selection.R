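#' Held-out prediction accuracy of an FC model
#'
#' The model-fit criterion used for hyperparameter selection, applied
#' identically to every estimator so that no method is favored by its own
#' fit metric.  The session is z-scored once, split into `n_folds`
#' contiguous blocks of timepoints, and for each fold an FC matrix is
#' estimated from the remaining folds.  Each node's held-out activity is
#' then predicted as the weighted sum of all other nodes' concurrent
#' held-out activities, using the node's FC row as regression coefficients,
#' and scored with the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` (no refit intercept).  Values are averaged
#' over nodes and folds.
#'
#' @inheritParams zscore_session
#' @param method Estimator label.
#' @param values Hyperparameter value(s) to evaluate (ignored for
#'   `"pairwise"`/`"partial"`); sharing the per-fold fit across a grid of
#'   values is much cheaper than repeated single fits.
#' @param n_folds Number of contiguous cross-validation folds.
#' @param ... Solver options passed through to the estimators.
#' @return A numeric vector of mean R-squared values, one per element of
#'   `values`, with the per-fold matrix in `attr(, "fold_r2")`.
#' @export
cv_r2 <- function(session, method, values = NULL, n_folds = 10, ...) {
  x <- zscore_matrix(session_data(session))
  n <- nrow(x)
  if (n < 2 * n_folds) {
    stop(sprintf("session too short for %d folds with >= 2 timepoints each",
                 n_folds), call. = FALSE)
  }
  if (method %in% c("pairwise", "partial")) values <- NA_real_
  stopifnot(length(values) >= 1)
  folds <- cv_fold_blocks(n, n_folds)
  r2 <- matrix(NA_real_, n_folds, length(values))
  for (f in seq_len(n_folds)) {
    te <- folds[[f]]
    xtr <- x[-te, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    blist <- tryCatch(
      fit_fc_path(xtr, method, values, ...),
      error = function(e) {
        stop(sprintf("fold %d: %s", f, conditionMessage(e)), call. = FALSE)
      })
    cte <- crossprod(xte) / nrow(xte)
    mte <- colMeans(xte)
    sstot <- diag(cte) - mte^2
    for (v in seq_along(values)) {
      b <- blist[[v]]
      cb <- rowSums(cte * b)           # diag(C %*% B), B symmetric
      bcb <- colSums(b * (cte %*% b))  # diag(B %*% C %*% B)
      ssres <- diag(cte) - 2 * cb + bcb
      r2[f, v] <- mean(1 - ssres / sstot)
    }
  }
  out <- colMeans(r2)
  attr(out, "fold_r2") <- r2
  out
}

# Deterministic contiguous fold blocks: sizes differ by at most one, larger
# blocks first.
cv_fold_blocks <- function(n, n_folds) {
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  purrr::map2(starts, ends, seq)
}

# Fit one training block for a whole grid of hyperparameter values,
# returning a list of symmetric zero-diagonal coefficient matrices.
# Regularized paths are warm-started inside the solvers.  CV fits use
# looser solver tolerances than final estimation (1e-3 / 1e-6 instead of
# 1e-5 / 1e-7): only the R-squared ranking matters here, and calibration
# runs showed identical selected values at a fraction of the cost.
fit_fc_path <- function(xtr, method, values, tol = NULL, maxit = 10000L,
                        inner_maxit = 1000L) {
  p <- ncol(xtr)
  if (method == "pairwise") {
    s <- cor(xtr); diag(s) <- 0
    return(list(s))
  }
  if (method == "partial") {
    if (nrow(xtr) <= p) {
      stop(sprintf(paste0("insufficient data: partial correlation requires ",
                          "more timepoints (T = %d) than nodes (p = %d)"),
                   nrow(xtr), p), call. = FALSE)
    }
    return(list(precision_to_parcor(solve(cor(xtr)))))
  }
  if (method == "glasso") {
    fit <- glasso_path_cpp(cor(xtr), values, tol %||% 1e-3,
                           as.integer(maxit), as.integer(inner_maxit))
    return(lapply(seq_along(values), function(i) fit$parcor[, , i]))
  }
  if (method == "gridge") {
    fit <- gridge_path_cpp(cor(xtr), values, tol %||% 1e-6,
                           as.integer(maxit))
    return(lapply(seq_along(values), function(i) fit$parcor[, , i]))
  }
  if (method == "pcreg") {
    return(pcreg_path(zscore_matrix(xtr), as.integer(values)))
  }
  stop("unknown method: ", method, call. = FALSE)
}

# PC-regression over a grid of component counts.  One eigendecomposition
# per target node of the shared centered cross-product matrix gives the
# principal axes (V) and score variances (eigenvalues d^2); because scores
# are orthogonal, the regression coefficient of each component is
# independent of how many are used, so nested models come for free.
pcreg_path <- function(x, ks) {
  p <- ncol(x)
  kmax <- max(ks)
  if (kmax > min(p - 1, nrow(x))) {
    stop(sprintf("n_components must be <= min(p - 1, T) = %d",
                 min(p - 1, nrow(x))), call. = FALSE)
  }
  xc <- sweep(x, 2, colMeans(x))
  cp <- crossprod(xc)
  rows <- vector("list", p)
  for (j in seq_len(p)) {
    e <- eigen(cp[-j, -j], symmetric = TRUE)
    v <- e$vectors[, seq_len(kmax), drop = FALSE]
    gamma <- as.vector(crossprod(v, cp[-j, j])) / e$values[seq_len(kmax)]
    rows[[j]] <- list(v = v, gamma = gamma)
  }
  lapply(ks, function(k) {
    b <- matrix(0, p, p)
    for (j in seq_len(p)) {
      b[j, -j] <- rows[[j]]$v[, seq_len(k), drop = FALSE] %*%
        rows[[j]]$gamma[seq_len(k)]
    }
    symmetrize(b)
  })
}

#' Select a regularization hyperparameter by cross-validation
#'
#' Evaluates [cv_r2()] over a grid of hyperparameter values and returns the
#' value with the highest mean held-out R-squared.  Grid steps follow the
#' per-method convention (0.005 for `lambda1`, 0.1 for `lambda2`, 5
#' components for PC regression).  If the maximizer falls on a grid
#' boundary, the grid is extended by one grid-width beyond that boundary
#' and the new values are evaluated, up to `max_expansions` times, so the
#' returned optimum is a local maximum interior to the final grid.  Hard
#' bounds are never crossed: penalties stay at or above one grid step, and
#' PC regression never uses fewer than 10 components nor more than
#' `min(p - 1, T)`.  A maximizer stuck on a hard bound (or remaining on a
#' boundary after the expansion cap) is returned with `boundary = TRUE`.
#'
#' Ties in R-squared resolve toward the least regularization (smallest
#' penalty, largest component count), which favors validity.
#'
#' @inheritParams cv_r2
#' @param initial_grid Optional numeric grid; defaults to
#'   `seq(0.005, 0.15, by = 0.005)` for glasso, `seq(0.1, 3, by = 0.1)` for
#'   graphical ridge, and `seq(10, p - 1, by = 5)` for PC regression.
#' @param max_expansions Cap on boundary expansions.
#' @return An `fc_selection`: list with `best_value`, `grid`,
#'   `mean_r2_per_value`, `fold_count`, `expansions`, `boundary`, `method`.
#' @export
select_hyperparameter <- function(session,
                                  method = c("glasso", "gridge", "pcreg"),
                                  initial_grid = NULL, n_folds = 10,
                                  max_expansions = 10, ...) {
  method <- match.arg(method)
  x <- session_data(session)
  p <- ncol(x)
  n_train <- nrow(x) - max(lengths(cv_fold_blocks(nrow(x), n_folds)))
  step <- switch(method, glasso = 0.005, gridge = 0.1, pcreg = 5)
  lower <- switch(method, glasso = 0.005, gridge = 0.1,
                  pcreg = min(10, p - 1))
  upper <- switch(method, glasso = Inf, gridge = Inf,
                  pcreg = min(p - 1, n_train))
  grid <- initial_grid %||% switch(method,
    glasso = seq(0.005, 0.15, by = 0.005),
    gridge = seq(0.1, 3, by = 0.1),
    pcreg = seq(min(10, p - 1), min(p - 1, n_train), by = 5))
  grid <- sort(unique(round(pmin(pmax(grid, lower), upper), 8)))
  if (method == "pcreg") grid <- unique(as.integer(round(grid)))

  evaluated <- numeric(0)
  r2 <- numeric(0)
  expansions <- 0L
  boundary <- FALSE
  repeat {
    todo <- setdiff(grid, evaluated)
    if (length(todo) > 0) {
      new_r2 <- as.numeric(cv_r2(session, method, todo,
                                 n_folds = n_folds, ...))
      evaluated <- c(evaluated, todo)
      r2 <- c(r2, new_r2)
      ord <- order(evaluated)
      evaluated <- evaluated[ord]
      r2 <- r2[ord]
    }
    ties <- which(r2 >= max(r2) - 1e-12)
    best <- if (method == "pcreg") evaluated[max(ties)] else
      evaluated[min(ties)]
    lo <- min(evaluated); hi <- max(evaluated)
    if (best > lo && best < hi) break
    if (expansions >= max_expansions) { boundary <- TRUE; break }
    width <- max(hi - lo, step)
    if (best <= lo) {
      from <- max(lower, lo - width); to <- lo - step
    } else {
      from <- hi + step; to <- min(upper, hi + width)
    }
    new_vals <- if (to >= from - 1e-9) round(seq(from, to, by = step), 8) else
      numeric(0)
    new_vals <- new_vals[new_vals >= lower - 1e-9 & new_vals <= upper + 1e-9]
    if (method == "pcreg") new_vals <- unique(as.integer(round(new_vals)))
    new_vals <- setdiff(new_vals, evaluated)
    if (length(new_vals) == 0) { boundary <- TRUE; break }
    grid <- sort(unique(c(evaluated, new_vals)))
    expansions <- expansions + 1L
  }
  structure(list(method = method, best_value = best, grid = evaluated,
                 mean_r2_per_value = r2, fold_count = n_folds,
                 expansions = expansions, boundary = boundary),
            class = "fc_selection")
}

#' @export
print.fc_selection <- function(x, ...) {
  cat(sprintf(
    "<fc_selection> %s: best = %g (mean CV R^2 = %.4f over %d folds)\n",
    x$method, x$best_value, max(x$mean_r2_per_value), x$fold_count))
  cat(sprintf("  grid of %d values, %d expansion(s)%s\n", length(x$grid),
              x$expansions,
              if (x$boundary) ", boundary maximum flagged" else ""))
  invisible(x)
}
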