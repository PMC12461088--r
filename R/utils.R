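# Internal helpers shared across modules.

# Deterministic seed splitting: child streams (sessions of a network,
# subjects of a cohort, ...) get seeds derived from the parent seed and an
# index through a Lehmer step, keeping everything inside 32-bit range.
child_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index)
  as.integer(s %% 2147483647L + 1)
}

# Strict upper-triangle vectorization used for all edge-level comparisons.
upper_tri_vec <- function(m) m[upper.tri(m)]

# Map from upper-triangle vector position back to (i, j) node pairs.
upper_tri_index <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  tibble::tibble(edge = seq_len(nrow(idx)), i = idx[, 1], j = idx[, 2])
}

# Extract the timepoints-by-nodes matrix from a session object or matrix.
session_data <- function(x) {
  if (inherits(x, "fc_session")) return(x$data)
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  stop("expected an fc_session, matrix or data frame of activities",
       call. = FALSE)
}

# Population-SD column standardization (divides by sqrt(mean((x - xbar)^2))).
zscore_matrix <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- sqrt(colSums(xc^2) / n)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad) > 0) {
    stop(sprintf("cannot z-score constant column(s): node %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sweep(xc, 2, s, "/")
}

spectral_radius <- function(w) {
  max(Mod(eigen(w, only.values = TRUE)$values))
}

symmetrize <- function(m) (m + t(m)) / 2

`%||%` <- function(a, b) if (is.null(a)) b else a
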