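# Internal helpers: seeded RNG scoping, child-seed derivation, clipping.

# Evaluate expr under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

# Documented counter scheme for reproducible sub-streams: child i of a master
# seed is drawn from a dedicated stream seeded by the master, so populations
# are reproducible and independent of evaluation order.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

clip1 <- function(x) pmin(1, pmax(-1, x))

# FNV-1a over a character scalar; used to stamp pipeline outputs with a
# config fingerprint without external dependencies.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}
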