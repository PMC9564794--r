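# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic per-stage seed forking: keeps derived seeds positive and
# below 2^31.
fork_seed <- function(seed, stage) {
  offsets <- c(generate = 101L, plant = 211L, bundle = 307L,
               detect = 401L, elbow = 503L)
  # double arithmetic: exact for any 32-bit seed, no integer overflow
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}
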