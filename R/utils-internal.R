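# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Row-wise softmax with max-subtraction for numerical stability.
row_softmax <- function(z) {
  z <- as.matrix(z)
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  ez <- exp(z - m)
  ez / rowSums(ez)
}

# Shannon entropy (nats) of a probability vector; 0 log 0 = 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Round half away from zero (round(0.5) -> 1), unlike base banker's rounding.
round_half_up <- function(x) floor(x + 0.5)

is_wholenumber <- function(x, tol = 1e-8) all(abs(x - round(x)) < tol)

`%||%` <- function(a, b) if (is.null(a)) b else a

one_hot <- function(idx, k) {
  out <- matrix(0, length(idx), k)
  out[cbind(seq_along(idx), idx + 1L)] <- 1
  out
}
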