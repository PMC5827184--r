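# Internal helpers shared across modules.

# Evaluate `code` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards. Keeps every seeded operation independent of global
# RNG usage elsewhere in the session.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Draws from a mean-zero normal truncated at +/- 2 standard deviations,
# via the inverse-CDF so a single runif stream determines the draws.
# Note the truncation shrinks the realized standard deviation to
# sd * sqrt(1 - 4*dnorm(2)/(pnorm(2)-pnorm(-2))) ~= 0.8796 * sd.
rtrunc_normal <- function(n, sd) {
  lo <- stats::pnorm(-2)
  hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

# Realized sd of the +/-2 sigma truncated normal, as a multiple of sigma.
trunc_normal_sd_factor <- function() {
  z <- stats::pnorm(2) - stats::pnorm(-2)
  sqrt(1 - 4 * stats::dnorm(2) / z)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
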