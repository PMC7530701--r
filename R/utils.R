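# Run code with a temporary RNG seed, restoring the caller's RNG state,
# so seeded generators are pure functions of their arguments.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage stream from one top-level seed by a fixed offset,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1103 * as.numeric(offset)) %% 2147483647)
}
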