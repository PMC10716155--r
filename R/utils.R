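# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic entry points route their
# randomness through this so no hidden global state leaks between calls.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, keeping the
# result inside the 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12289) %% 2147483629)
}

# Plug-in Shannon entropy (bits) of a probability vector; zero-probability
# entries contribute nothing.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
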