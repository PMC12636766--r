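# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All R-level randomness in the package
# goes through this, so a config seed fully determines a run.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
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
  set.seed(seed)
  code
}

# Counter-based derivation of sub-stream seeds from one master seed.
# Kept below 2^31 so the result is always a valid R integer seed.
derive_seed <- function(seed, counter) {
  v <- (as.double(seed) %% 2147483647) * 48271 + 97 * as.double(counter)
  as.integer(v %% 2147483629) + 1L
}

# Round half away from zero (used to realize the target magnetization as an
# exact integer composition).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
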