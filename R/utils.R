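# Seed plumbing.  All stochastic operations take an integer seed and run
# under a locally-set RNG state, restoring the caller's state afterwards.
# Named substreams derive per-unit seeds (one per individual per chromosome)
# from the base seed and a label, so adding individuals to a config does not
# perturb the draws of existing ones.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic string hash -> integer in [0, 2^31 - 2], independent of R
# internals (polynomial rolling hash mod the Mersenne prime 2^31 - 1;
# multiplier kept small so double arithmetic stays exact).
hash_label <- function(label) {
  bytes <- utf8ToInt(label)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

substream_seed <- function(base_seed, ...) {
  label <- paste(..., sep = "/")
  as.integer(((as.numeric(base_seed) %% 2147483647) * 48271 +
                hash_label(label)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
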