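# Shared fixtures built in code. The full-scale default study is expensive,
# so it is built lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

get_default_study <- function(seed = 1) {
  key <- paste0("study_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_default_study(seed = seed)
  }
  .fixture_cache[[key]]
}

# Small planted instance for fast unit tests.
small_cohort <- function(seed = 1, n_genes = 200, n_tfs = 30, T_ = 20,
                         K_true = 3, target_r2 = 0.5) {
  simulate_default_study(seed = seed, n_genes = n_genes, n_tfs = n_tfs,
                         T_ = T_, K_true = K_true, target_r2 = target_r2)
}

# Random regression instance with consistent shapes.
random_instance <- function(N = 30, d = 6, K = 2, T_ = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(N * d), N, d, dimnames = list(NULL, paste0("tf", 1:d)))
    L <- matrix(rnorm(d * K), d, K)
    S <- matrix(rnorm(K * T_), K, T_)
    Y <- matrix(rnorm(N * T_), N, T_, dimnames = list(NULL, paste0("s", 1:T_)))
    list(X = X, L = L, S = S, Y = Y)
  })
}

# Agreement of two partitions up to relabeling (adjusted Rand == 1).
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Mid-size cohort used by the frozen cross-validation reference test.
get_default_study_small_cv <- function() {
  if (is.null(.fixture_cache$study_cv)) {
    .fixture_cache$study_cv <- simulate_default_study(
      seed = 31, n_genes = 300, n_tfs = 20, T_ = 12, K_true = 2)
  }
  .fixture_cache$study_cv
}
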