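# Internal helpers: seeded substreams and RNG hygiene.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers the global stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a character id, folded with a top-level seed.
# Used to derive one independent substream per sample for rarefaction so that
# results do not depend on sample order. Arithmetic stays below 2^53, so the
# double-precision modular fold is exact.
substream_seed <- function(seed, id) {
  bytes <- utf8ToInt(as.character(id))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer((h * 1000003 + (seed %% 2147483647)) %% 2147483646 + 1)
}

# One sub-seed per permutation index, drawn sequentially from a stream seeded
# with `seed`: extending n_perm leaves earlier sub-seeds (hence earlier draws)
# unchanged.
perm_seeds <- function(seed, n_perm) {
  with_local_seed(seed, sample.int(2147483646L, n_perm, replace = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sym_log <- function(...) message("[sympref] ", ...)
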