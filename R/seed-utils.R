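# RNG discipline: every stochastic entry point takes an explicit seed, runs in
# a local RNG scope (the global .Random.seed is saved and restored), and
# per-case streams are derived by integer mixing so cohort generation is
# order-independent.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Mix a base seed with a stream index into a 31-bit seed.
mix_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 65537
  as.integer(s %% 2147483647)
}
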