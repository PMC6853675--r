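## Internal helpers: local RNG streams and derived seeds.

## Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## One reproducible sub-seed per iteration, derived from the master seed so
## iterations form independent, individually re-runnable streams.
iterationSeeds <- function(seed, n) {
  withLocalSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1 || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
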