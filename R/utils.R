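# Seed hygiene: every stochastic entry point evaluates under a local RNG
# state so calls are reproducible without disturbing the caller's stream.

with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic sub-seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103 + k * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
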