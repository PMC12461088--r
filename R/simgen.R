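#' Generate a modular scale-free ground-truth network
#'
#' Builds a directed, weighted ground-truth connectivity matrix `W` with the
#' community structure used by the simulation benchmarks: `n_modules`
#' modules grown independently by Barabasi-Albert preferential attachment,
#' then connected by a fixed budget of extra-modular edges whose endpoints
#' are again drawn proportionally to node degree.  The binary skeleton is
#' undirected (every structural edge exists in both directions) but each
#' direction receives its own Gaussian weight, so `W` is asymmetric.
#'
#' Per module, growth starts from `seed_size` fully connected nodes and adds
#' one node at a time, each bringing `growth_edges` edges that attach to
#' existing nodes with probability proportional to current degree
#' (`k_i / sum_j k_j`), sampled without replacement.  With the defaults
#' (5 modules of 20 nodes, seed 4, 4 edges per new node) every generated
#' network has exactly 700 directed intra-modular edges (36.84% of possible
#' intra-modular connections) and 186 directed extra-modular edges.
#'
#' Weights are drawn per directed edge from `Normal(intra_mean, weight_sd)`
#' or `Normal(extra_mean, weight_sd)`; one randomly chosen module is
#' inhibitory, its extra-modular edges (incoming and outgoing) multiplied by
#' -1.  All weights are then divided by the network mean over nodes of the
#' summed incoming weights and multiplied by `scale`, which
#' keeps the linear activity model `X = (I - W)^-1 E` stable.  Networks
#' whose spectral radius still reaches 1 are regenerated from a derived
#' seed; the attempt count is recorded in `meta`.
#'
#' @param p Number of nodes; must equal `n_modules * module_size`.
#' @param n_modules,module_size Community structure.
#' @param seed_size Nodes in the fully connected seed of each module.
#' @param growth_edges Edges attached by each newly added node (`m` of the
#'   Barabasi-Albert model).
#' @param extra_modular_edges Target number of *directed* extra-modular
#'   edges; must be even (edges are added as bidirectional pairs).
#' @param intra_mean,extra_mean,weight_sd Weight distribution parameters.
#' @param scale Global scaling applied after normalization.
#' @param normalize Either `"signed"` (default; normalize by the network
#'   mean of summed raw incoming weights) or `"absolute"` (mean of summed
#'   absolute incoming weights).  See the methods vignette for why signed
#'   sums are the default.
#' @param seed Integer seed; generation is fully reproducible.
#' @param max_attempts Regeneration cap for the stability check.
#'
#' @return An object of class `fc_network`: a list with elements `weights`
#'   (p x p matrix, `weights[i, j]` is the influence of node `j` on node
#'   `i`; zero diagonal), `module` (integer module label per node),
#'   `inhibitory_module`, and `meta` (generation parameters and counts).
#' @examples
#' net <- generate_network(seed = 42)
#' net$meta$n_intra_directed  # 700
#' @export
generate_network <- function(p = 100, n_modules = 5, module_size = 20,
                             seed_size = 4, growth_edges = 4,
                             extra_modular_edges = 186,
                             intra_mean = 1, extra_mean = 0.5, weight_sd = 1,
                             scale = 0.6,
                             normalize = c("signed", "absolute"),
                             seed = 1L, max_attempts = 100L) {
  normalize <- match.arg(normalize)
  stopifnot(p == n_modules * module_size,
            module_size > growth_edges, growth_edges >= 1,
            growth_edges <= seed_size, seed_size <= module_size,
            extra_modular_edges >= 0, scale > 0)
  if (extra_modular_edges %% 2 != 0) {
    stop("extra_modular_edges is a directed count; it must be even",
         call. = FALSE)
  }
  n_pairs <- extra_modular_edges / 2
  max_cross_pairs <- (p^2 - n_modules * module_size^2) / 2
  if (n_pairs > max_cross_pairs) {
    stop("extra_modular_edges exceeds the number of available ",
         "cross-module node pairs", call. = FALSE)
  }
  module <- rep(seq_len(n_modules), each = module_size)

  for (attempt in seq_len(max_attempts)) {
    set.seed(child_seed(seed, attempt - 1L))
    adj <- matrix(FALSE, p, p)

    # per-module preferential-attachment growth
    for (m in seq_len(n_modules)) {
      nodes <- which(module == m)
      seeds <- nodes[seq_len(seed_size)]
      adj[seeds, seeds] <- TRUE
      diag(adj)[seeds] <- FALSE
      for (v in nodes[-seq_len(seed_size)]) {
        existing <- nodes[nodes < v]
        deg <- colSums(adj[, existing, drop = FALSE])
        targets <- preferential_sample(existing, growth_edges, deg)
        adj[v, targets] <- TRUE
        adj[targets, v] <- TRUE
      }
    }

    # extra-modular edges, both endpoints degree-weighted
    added <- 0L
    guard <- 0L
    deg <- colSums(adj)
    while (added < n_pairs) {
      guard <- guard + 1L
      if (guard > 10000L * max(n_pairs, 1L)) {
        stop("could not place the requested extra-modular edges",
             call. = FALSE)
      }
      a <- preferential_sample(seq_len(p), 1L, deg)
      b <- preferential_sample(seq_len(p), 1L, deg)
      if (a == b || module[a] == module[b] || adj[a, b]) next
      adj[a, b] <- TRUE
      adj[b, a] <- TRUE
      deg[c(a, b)] <- deg[c(a, b)] + 1L
      added <- added + 1L
    }

    # directed Gaussian weights over the bidirectional skeleton
    intra <- outer(module, module, "==") & adj
    w <- matrix(0, p, p)
    n_in <- sum(intra)
    n_ex <- sum(adj) - n_in
    w[intra] <- rnorm(n_in, intra_mean, weight_sd)
    w[adj & !intra] <- rnorm(n_ex, extra_mean, weight_sd)

    inhib <- sample.int(n_modules, 1)
    flip <- (module == inhib)
    ex_mask <- adj & !intra
    w[ex_mask & (outer(flip, rep(TRUE, p)) | outer(rep(TRUE, p), flip))] <-
      -w[ex_mask & (outer(flip, rep(TRUE, p)) | outer(rep(TRUE, p), flip))]

    norm <- switch(normalize,
                   absolute = mean(rowSums(abs(w))),
                   signed = mean(rowSums(w)))
    if (!is.finite(norm) || abs(norm) < .Machine$double.eps) {
      next  # degenerate normalizer; retry with a new draw
    }
    w <- w / norm * scale
    rho <- spectral_radius(w)
    if (rho < 1) {
      return(structure(list(
        weights = w,
        module = module,
        inhibitory_module = inhib,
        meta = list(p = p, n_modules = n_modules, module_size = module_size,
                    seed_size = seed_size, growth_edges = growth_edges,
                    extra_modular_edges = extra_modular_edges,
                    intra_mean = intra_mean, extra_mean = extra_mean,
                    weight_sd = weight_sd, scale = scale,
                    normalize = normalize, seed = seed,
                    attempts = attempt, spectral_radius = rho,
                    n_intra_directed = n_in, n_extra_directed = n_ex)),
        class = "fc_network"))
    }
  }
  stop("failed to generate a stable network (spectral radius < 1) within ",
       max_attempts, " attempts", call. = FALSE)
}

# Weighted sampling without replacement proportional to degree; nodes with
# zero degree never attract edges (cannot occur after the seed clique).
preferential_sample <- function(nodes, size, degree) {
  if (length(nodes) == 1) return(rep(nodes, size))
  nodes[sample.int(length(nodes), size, prob = degree)]
}

#' @export
print.fc_network <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<fc_network> %d nodes, %d modules of %d (module %d inhibitory)\n",
    m$p, m$n_modules, m$module_size, x$inhibitory_module))
  cat(sprintf("  %d intra- + %d extra-modular directed edges; ",
              m$n_intra_directed, m$n_extra_directed))
  cat(sprintf("spectral radius %.3f (seed %d, %d attempt(s))\n",
              m$spectral_radius, m$seed, m$attempts))
  invisible(x)
}

#' Simulate an activity session from a ground-truth network
#'
#' Draws i.i.d. standard-normal intrinsic activity `E` (one row per
#' timepoint) and mixes it through the network with the linear structural
#' model `x_t = (I - W)^-1 e_t`, applied timepoint-wise.  Gaussian
#' measurement noise is then added per node with standard deviation
#' `noise_level` times that node's noiseless series SD, so `noise_level =
#' 0.5` corresponds to noise with roughly half the signal amplitude.
#'
#' @param net An [fc_network][generate_network].
#' @param n_timepoints Number of rows of the returned activity matrix.
#' @param noise_level Nonnegative measurement-noise ratio.
#' @param seed Integer seed.
#' @return An `fc_session`: list with `data` (timepoints x nodes matrix),
#'   `noise_level`, `seed`, `tr` (NULL for the plain linear model) and
#'   `network_seed`.
#' @export
simulate_session <- function(net, n_timepoints = 250, noise_level = 0.5,
                             seed = 1L) {
  stopifnot(inherits(net, "fc_network"), n_timepoints >= 1, noise_level >= 0)
  w <- net$weights
  p <- ncol(w)
  mix <- t(solve(diag(p) - w))
  set.seed(seed)
  e <- matrix(rnorm(n_timepoints * p), n_timepoints, p)
  x <- e %*% mix
  if (noise_level > 0) {
    sds <- apply(x, 2, sd)
    noise <- matrix(rnorm(n_timepoints * p), n_timepoints, p)
    x <- x + sweep(noise, 2, noise_level * sds, "*")
  }
  structure(list(data = x, noise_level = noise_level, seed = seed,
                 tr = NULL, network_seed = net$meta$seed),
            class = "fc_session")
}

#' Simulate a haemodynamically filtered session
#'
#' A BOLD-like variant of [simulate_session()]: each node's intrinsic
#' activity is a binary up/down state train generated by an alternating
#' renewal process with exponential holding times (means `up_mean_s` and
#' `down_mean_s`), plus Gaussian neural noise with SD equal to
#' `neural_noise_frac` times the up/down state difference.  The network
#' mixing `(I - W)^-1` is applied at every fine timestep, the mixed series
#' is convolved with a canonical double-gamma haemodynamic response
#' function (peak 6 s, undershoot 16 s, undershoot ratio 1/6), downsampled
#' from `dt` to `tr`, and finally measurement noise is added as in
#' [simulate_session()].
#'
#' @inheritParams simulate_session
#' @param duration_s Simulated duration in seconds.
#' @param dt Neural sampling interval in seconds; must divide `tr`.
#' @param tr Output sampling interval in seconds.
#' @param up_mean_s,down_mean_s Mean holding times of the up/down states.
#' @param neural_noise_frac Neural noise SD as a fraction of the state
#'   difference.
#' @return An `fc_session` with `tr` set; `nrow(data) == floor(duration_s/tr)`.
#' @export
simulate_hrf_session <- function(net, duration_s = 600, dt = 0.05, tr = 2,
                                 up_mean_s = 2.5, down_mean_s = 10,
                                 neural_noise_frac = 0.05,
                                 noise_level = 0.5, seed = 1L) {
  stopifnot(inherits(net, "fc_network"), duration_s > tr, dt > 0, tr > 0)
  if (abs(tr / dt - round(tr / dt)) > 1e-8) {
    stop("dt must divide tr", call. = FALSE)
  }
  w <- net$weights
  p <- ncol(w)
  n_fine <- round(duration_s / dt)
  set.seed(seed)
  states <- vapply(seq_len(p), function(i) {
    binary_state_train(n_fine, dt, up_mean_s, down_mean_s)
  }, numeric(n_fine))
  if (neural_noise_frac > 0) {
    states <- states + matrix(rnorm(n_fine * p, sd = neural_noise_frac),
                              n_fine, p)
  }
  x <- states %*% t(solve(diag(p) - w))
  h <- canonical_hrf(dt)
  x <- apply(x, 2, function(col) {
    stats::convolve(col, rev(h), type = "open")[seq_len(n_fine)]
  })
  step <- round(tr / dt)
  n_out <- floor(duration_s / tr)
  x <- x[(seq_len(n_out) - 1L) * step + 1L, , drop = FALSE]
  if (noise_level > 0) {
    sds <- apply(x, 2, sd)
    noise <- matrix(rnorm(n_out * p), n_out, p)
    x <- x + sweep(noise, 2, noise_level * sds, "*")
  }
  structure(list(data = x, noise_level = noise_level, seed = seed,
                 tr = tr, network_seed = net$meta$seed),
            class = "fc_session")
}

# Alternating up (1) / down (0) binary train; exponential holding times.
# Initial state drawn from the stationary occupancy up/(up+down).
binary_state_train <- function(n, dt, up_mean, down_mean) {
  out <- numeric(n)
  state <- runif(1) < up_mean / (up_mean + down_mean)
  t_pos <- 1L
  while (t_pos <= n) {
    hold <- max(1L, round(rexp(1, rate = 1 / ifelse(state, up_mean,
                                                    down_mean)) / dt))
    out[t_pos:min(n, t_pos + hold - 1L)] <- as.numeric(state)
    t_pos <- t_pos + hold
    state <- !state
  }
  out
}

# Canonical double-gamma HRF sampled at dt (peak 6 s, undershoot 16 s,
# undershoot ratio 1/6), 32 s support, peak-normalized.
canonical_hrf <- function(dt, length_s = 32) {
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' @export
print.fc_session <- function(x, ...) {
  cat(sprintf("<fc_session> %d timepoints x %d nodes (noise %.2f%s)\n",
              nrow(x$data), ncol(x$data), x$noise_level,
              if (is.null(x$tr)) "" else sprintf(", TR %gs", x$tr)))
  invisible(x)
}
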