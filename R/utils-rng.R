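# Seeded-RNG plumbing. Every stochastic entry point takes one integer seed;
# sub-seeds for per-injection draws are derived arithmetically so that a
# dataset is reproducible injection-by-injection, not just as a whole.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed in [0, 2^31 - 2]; a distinct stream per
# (seed, index, stream-tag) triple.
derive_seed <- function(seed, index, stream = 0L) {
  m <- 2147483647
  s <- (as.double(seed) %% m) * 48271 %% m
  s <- (s + as.double(index) * 69621) %% m
  s <- (s * 48271 + as.double(stream) * 16807) %% m
  as.integer(s %% (m - 1))
}
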