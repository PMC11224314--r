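# Seeding and small shared helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All randomness in the package flows through
# this, so every artifact is a pure function of its recorded seed.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, staying within
# the 32-bit integer range. Distinct labels give distinct, reproducible
# streams (used so fold k's training does not share the split's stream).
deriveSeed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label))) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435.0 + h) %% .Machine$integer.max)
}

# half-up rounding to `digits` decimals (matches how the reference tables
# print values; R's round() uses round-half-even)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
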