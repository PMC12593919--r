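# Internal helpers: seed handling and small numeric utilities.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# stream is restored afterwards. seed = NULL runs in the ambient stream.
withSeed <- function(seed, code) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed)))
    return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# Fixed-offset seed streams: one stream per generator layer so regenerating
# one layer never perturbs another. Kept below 2^31 - 1.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647) * 7919 + offset) %% 2147483646L + 1L
}

# Round half-up to `digits` decimals (base round() is half-even).
roundHalfUp <- function(x, digits = 1L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
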