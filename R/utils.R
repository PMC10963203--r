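# Internal helpers shared across modules.

# Commercial rounding: floor(x + 0.5).  round() in R rounds half to even,
# which would give 4 non-respondents in a 15-unit domain at rate 0.30; the
# reference stratum counts require 5.
round_half_up <- function(x) floor(x + 0.5)

# Run `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream" so that seeded outer calls can
# drive unseeded inner ones deterministically.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Standardized third central moment (biased denominator); positive for
# right-skewed samples.
sample_skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
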