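# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package functions never perturb the session stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(code)
}

# Deterministic sub-seed derivation so one pipeline seed drives every stage
# without reusing the same stream. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + offset) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
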