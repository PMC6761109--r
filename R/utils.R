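# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1009 * as.double(k)) %% 2147483647)
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}

check_scalar <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (x < lower || (!allow_zero && x == lower)) {
    abort(sprintf("`%s` must be %s %s.", name,
                  if (allow_zero) ">=" else ">", format(lower)))
  }
  invisible(x)
}

soft_threshold <- function(z, gamma) {
  sign(z) * pmax(abs(z) - gamma, 0)
}

# Frobenius / L1 norms on matrices
fnorm2 <- function(m) sum(m * m)
l1norm <- function(m) sum(abs(m))
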