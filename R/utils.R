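# Seeding helpers. Pools and introduction orders use counter-based child
# seeds derived from a single master seed, so pool k is reproducible on its
# own without generating pools 1..k-1.

# Deterministic child seed from (master, counter), kept in [1, 2^31 - 2].
derive_seed <- function(master, counter) {
  m <- 2^31 - 1
  x <- (as.double(master) %% m) * 48271 %% m
  x <- (x + as.double(counter) * 16807) %% m
  x <- (x * 69621) %% m
  as.integer(x %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state.
with_seed <- function(seed, expr) {
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
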