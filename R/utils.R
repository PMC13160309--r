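# Internal numerical helpers shared across modules.

# Row-wise softmax with max-subtraction; exponentials floored at a tiny
# positive value so weights stay strictly positive even for score gaps far
# beyond exp's underflow point (~745).
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- pmax(exp(m), 1e-300)
  e / rowSums(e)
}

# Softmax of a plain vector.
softmax_vec <- function(v) {
  v <- v - max(v)
  e <- pmax(exp(v), 1e-300)
  e / sum(e)
}

# Repeat a length-R vector as each row of a B x R matrix.
rep_row <- function(v, n) matrix(v, nrow = n, ncol = length(v), byrow = TRUE)

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
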