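# Internal RNG helpers: every stochastic step in the package draws from a
# locally seeded generator and restores the caller's RNG state, so pipelines
# are bit-reproducible from their `seed` arguments without clobbering the
# user's session RNG.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
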