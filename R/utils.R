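# Small internal helpers: a platform-independent string hash mapped to
# uniform deviates (used for the deterministic stereo perturbation field),
# and a local-RNG evaluation guard.

## Park-Miller style byte-fed hash, modulus 2^31 - 1. All arithmetic stays
## below 2^53 so the result is exact in double precision on every platform;
## no global RNG state is touched.
.hash31 <- function(key) {
  m <- 2147483647
  h <- 17
  for (b in utf8ToInt(key)) {
    h <- (h * 48271 + b + 1) %% m
  }
  # a few extra scrambling rounds so short keys diffuse
  for (i in 1:3) h <- (h * 48271 + 11) %% m
  h
}

## uniform deviate in [-1, 1] from a string key, deterministic across platforms
.hashUnit <- function(key) {
  2 * .hash31(key) / 2147483646 - 1
}

## evaluate `expr` with the global RNG seeded to `seed`, restoring any
## pre-existing RNG state afterwards
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
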