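# Internal helpers.

# Deterministic per-stage / per-unit seed derivation from one master seed.
# Keeps derived seeds in 32-bit range. The offsets give independent streams
# for synthesis, rating simulation, etc.
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  ((as.double(seed) * 69069 + stream * 10007 + index * 101) %% 2147483647) + 1
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate an expression with a local RNG state (restores .Random.seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

fisher_z <- function(r, clamp = 1 - 1e-12) {
  atanh(clip(r, -clamp, clamp))
}
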