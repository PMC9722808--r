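# Internal helpers: deterministic seed streams and RNG hygiene.

# Derive a per-unit seed from a global seed and a unit index, keeping the
# result a valid 32-bit R integer. Lehmer-style mixing; collisions across
# realistic cohort sizes are astronomically unlikely to matter since the
# derived value only seeds Mersenne-Twister.
derive_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) + 1
  v <- (s * 48271 + as.double(i) * 9973 + 12345) %% 2147483647
  as.integer(v)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

# All nonempty subsets of 1..n as a list of integer vectors (n <= 16).
all_on_sets <- function(n) {
  bits <- bitwShiftL(1L, 0:(n - 1))
  lapply(seq_len(2^n - 1), function(m) which(bitwAnd(m, bits) != 0L))
}
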