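## Small-world datasets shared across test files. Sizes are deliberately
## modest so the default suite stays fast; the acceptance tests use larger
## draws.

small_k2 <- function(n = 800, seed = 42, ...) {
  make_scenario("baseline_k2", overrides = list(n_samples = n, ...), seed = seed)
}

small_k1 <- function(n = 800, seed = 42, ...) {
  make_scenario("baseline_k1", overrides = list(n_samples = n, ...), seed = seed)
}

## one-hot matrix from integer labels
onehot <- function(z, K = max(z)) {
  Z <- matrix(0, length(z), K)
  Z[cbind(seq_along(z), z)] <- 1
  Z
}

## fast fitting options for tests
fast_opts <- function(K, seed = 1, ...) {
  mfmr_opts(K = K, n_restarts = 1L, rel_tol = 1e-7, max_iter = 300L,
            seed = seed, ...)
}
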