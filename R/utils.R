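# internal helpers

# Run `code` under a local RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable sub-seed for a named pipeline stage, so stages can be re-run in
# isolation while a single global seed governs the whole run.  Kept below
# 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
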