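# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All randomness in the package flows through this
# so that a seed in a config fully determines the output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Derive `k` child seeds (< 2^31) deterministically from one base seed.
derive_seeds <- function(base_seed, k) {
  with_seed(base_seed, sample.int(.Machine$integer.max - 1L, k))
}

expit <- function(x) 1 / (1 + exp(-x))

# Numerically safe log(sigmoid) pair used by the cross-entropy loss.
log_expit <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))

assert_probability <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", what))
  }
  invisible(x)
}

assert_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive.", what))
  }
  invisible(x)
}

# Population standard deviation (divide by n, not n - 1); used when
# standardizing continuous covariates.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

`%g0%` <- function(x, default) if (length(x) == 0 || is.null(x)) default else x
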