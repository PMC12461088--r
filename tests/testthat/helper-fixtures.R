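# Shared fixtures: everything is generated in code at test time.

# Small 20-node network (4 modules of 5) that keeps estimator tests fast.
tiny_net <- function(seed = 1L, ...) {
  generate_network(p = 20, n_modules = 4, module_size = 5, seed_size = 3,
                   growth_edges = 2, extra_modular_edges = 8, seed = seed,
                   ...)
}

# Hand-built network wrapper for fully controlled weight matrices.
manual_net <- function(w, module = rep(1L, nrow(w))) {
  structure(list(weights = w, module = module, inhibitory_module = 1L,
                 meta = list(p = nrow(w), n_modules = length(unique(module)),
                             module_size = nrow(w), seed = 0L,
                             spectral_radius = max(Mod(eigen(
                               w, only.values = TRUE)$values)),
                             n_intra_directed = sum(w != 0),
                             n_extra_directed = 0L)),
            class = "fc_network")
}

# Correlated multi-node test data with known covariance structure.
gaussian_session <- function(n, sigma, seed = 1L) {
  set.seed(seed)
  p <- nrow(sigma)
  ch <- chol(sigma)
  matrix(rnorm(n * p), n, p) %*% ch
}
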