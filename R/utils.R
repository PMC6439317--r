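# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. All stochastic generators funnel through this so that
# identical (config, seed) pairs give identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic fan-out of one global seed into per-stage seeds (< 2^31).
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 1009 + stage * 9973) %% 2147483647
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min),
          class = "feconet_invalid_argument")
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s.", name, min),
          class = "feconet_invalid_argument")
  }
  as.numeric(x)
}

# Round half away from zero (printed percentages use half-up, not banker's).
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
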