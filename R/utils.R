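# Internal numerical helpers.

# Row-wise log-sum-exp of a matrix; returns a vector of length nrow(x).
row_logsumexp <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  out <- m + log(rowSums(exp(x - m)))
  # all -Inf rows: exp(-Inf - -Inf) = NaN; such a row has probability zero
  out[!is.finite(m)] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic substream seeds derived from one user seed; kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647
}

# Evaluate fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards (the public API takes explicit seeds so pipelines
# remain reproducible regardless of ambient RNG use).
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  fn()
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}
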