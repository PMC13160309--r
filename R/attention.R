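#' Initialize rule-level self-attention parameters for one view
#'
#' The rule-attention block treats an input feature vector \eqn{x \in R^D} as
#' a sequence of length one, runs multi-head self-attention over it, and maps
#' the attended representation to one score per rule; a softmax over those
#' scores yields per-sample rule importance weights. Because the "sequence"
#' has a single token, each head's attention softmax puts weight 1 on its only
#' key, so \eqn{Head_i = x W_i^V} analytically — the structure is kept anyway
#' so the block generalizes to rule-token sequences.
#'
#' If \code{D} is not divisible by \code{n_heads}, the head count is reduced
#' to the largest divisor of \code{D} not exceeding the request (with a
#' message), so head width \code{D / H} is always integral.
#'
#' @param D input feature dimension of the view.
#' @param R number of rules scored.
#' @param n_heads requested number of attention heads (default 4).
#' @param seed integer seed for the symmetric small-variance initialization.
#' @param init_sd standard deviation of the Gaussian init for the projection
#'   matrices. The rule-score head \code{W_fc}/\code{b_fc} starts at zero so
#'   the initial attention weights are exactly uniform (the no-attention
#'   reduction).
#' @return An object of class \code{"attention_params"} with per-head
#'   projection lists \code{Wq}, \code{Wk}, \code{Wv} (\code{[D x D/H]} each),
#'   output projection \code{Wo} \code{[D x D]}, score head \code{Wfc}
#'   \code{[D x R]}, \code{bfc} \code{[R]}, and \code{n_heads}.
#' @export
attention_params <- function(D, R, n_heads = 4L, seed = 1L, init_sd = 0.1) {
  H <- largest_divisor_upto(D, n_heads)
  if (H != n_heads)
    message(sprintf("n_heads reduced from %d to %d so that head width divides D = %d",
                    n_heads, H, D))
  dk <- D %/% H
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  proj <- function() matrix(stats::rnorm(D * dk, sd = init_sd), D, dk)
  head_list <- function() stats::setNames(replicate(H, proj(), simplify = FALSE),
                                          paste0("h", seq_len(H)))
  structure(
    list(
      Wq = head_list(),
      Wk = head_list(),
      Wv = head_list(),
      Wo = matrix(stats::rnorm(D * D, sd = init_sd), D, D),
      Wfc = matrix(0, D, R),
      bfc = numeric(R),
      n_heads = H, D = D, R = R
    ),
    class = "attention_params"
  )
}

largest_divisor_upto <- function(D, h) {
  D <- as.integer(D)
  h <- min(as.integer(h), D)
  while (h > 1L && D %% h != 0L) h <- h - 1L
  max(h, 1L)
}

#' Multi-head self-attention over a single-token sequence
#'
#' Computes \eqn{h = Concat(Head_1, ..., Head_H) W^O} with
#' \eqn{Head_i = Attention(x W_i^Q, x W_i^K, x W_i^V)} using scaled
#' dot-product attention. With sequence length one the attention softmax is
#' degenerate (weight 1 on the single key) and the output reduces to
#' \eqn{Concat_i(x W_i^V) W^O}; the scaled dot-product path is executed
#' regardless, for structural fidelity.
#'
#' @param x finite numeric vector of length \code{D} (or a \code{[B x D]}
#'   matrix for a batch).
#' @param params an [attention_params()].
#' @return Attended features: a length-\code{D} vector (or \code{[B x D]}
#'   matrix matching the input).
#' @export
attend <- function(x, params) {
  stopifnot(inherits(params, "attention_params"))
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != params$D)
    stop(sprintf("input has %d features but attention expects %d", ncol(X), params$D),
         call. = FALSE)
  stop_if_not_finite(X, "x")
  H <- attend_batch(X, params)
  if (vec_in) drop(H) else H
}

# Batched single-token MHSA. Each row of X is its own length-1 sequence.
attend_batch <- function(X, params) {
  dk <- params$D %/% params$n_heads
  heads <- vector("list", params$n_heads)
  for (i in seq_len(params$n_heads)) {
    Q <- X %*% params$Wq[[i]]
    K <- X %*% params$Wk[[i]]
    V <- X %*% params$Wv[[i]]
    score <- rowSums(Q * K) / sqrt(dk)      # [B]: the 1x1 attention logit
    w <- exp(score - score)                 # softmax over the single key: 1
    heads[[i]] <- w * V
  }
  do.call(cbind, heads) %*% params$Wo
}

#' Per-sample rule attention weights
#'
#' Maps attended features to rule scores through a linear head,
#' \eqn{s = h W_{fc} + b_{fc}}, then softmax-normalizes the scores into rule
#' attention weights \eqn{\alpha} on the \code{R}-simplex.
#'
#' @param x finite numeric vector of length \code{D}.
#' @param params an [attention_params()].
#' @return An object of class \code{"rule_attention"}: list with
#'   \code{attended} (length \code{D}), \code{scores} (length \code{R}) and
#'   \code{weights} \eqn{\alpha} (length \code{R}, positive, summing to 1).
#' @export
rule_weights <- function(x, params) {
  h <- attend(x, params)
  s <- drop(h %*% params$Wfc) + params$bfc
  structure(
    list(attended = h, scores = s, weights = softmax_vec(s)),
    class = "rule_attention"
  )
}

#' @export
print.rule_attention <- function(x, ...) {
  cat(sprintf("Rule attention over %d rules; entropy %.4f nats (max %.4f)\n",
              length(x$weights), attention_entropy(x$weights), log(length(x$weights))))
  invisible(x)
}
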