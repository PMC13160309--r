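#' Learnable view weights
#'
#' Views are fused by a convex combination whose coefficients
#' \eqn{\beta^{(v)}} are the softmax of unconstrained logits, one logit per
#' view; training updates the logits end-to-end. Equal logits (the
#' initialization) give uniform weights.
#'
#' @param logits numeric vector of unnormalized view importances, length
#'   \code{V}.
#' @return An object of class \code{"view_weights"}: list with \code{logits}
#'   and the normalized simplex vector \code{beta}.
#' @export
view_weights <- function(logits) {
  stop_if_not_finite(logits, "logits")
  structure(list(logits = as.numeric(logits), beta = softmax_vec(logits)),
            class = "view_weights")
}

#' @export
print.view_weights <- function(x, ...) {
  cat("View weights (beta):", paste(sprintf("%.4f", x$beta), collapse = " "), "\n")
  invisible(x)
}

#' Attention-modulated rule activation for one view
#'
#' Combines a view's rule attention weights with its rule firing:
#' the element-wise product \eqn{\alpha \odot \ln a} is softmax-normalized
#' over rules, giving a simplex-valued activation vector. When attention is
#' disabled (\eqn{\alpha} replaced by the all-ones vector), the softmax of the
#' raw log-firing recovers exactly the classic normalized firing
#' \eqn{a_r / \sum_j a_j} of a standard TSK system, via the softmax-log
#' identity.
#'
#' @param log_firing numeric vector of length \code{R}; rule log-firing
#'   strengths (components \code{<= 0}).
#' @param alpha numeric vector of length \code{R}; rule attention weights (on
#'   the simplex), or the all-ones vector for the no-attention reduction.
#' @param domain \code{"log"} (default) modulates the log-firing,
#'   \code{softmax(alpha * log_firing)}; \code{"linear"} modulates the
#'   exponentiated firing, \code{softmax(alpha * exp(log_firing))}.
#' @return Simplex vector of length \code{R}.
#' @export
view_activation <- function(log_firing, alpha, domain = c("log", "linear")) {
  domain <- match.arg(domain)
  if (length(log_firing) != length(alpha))
    stop("log_firing and alpha must have equal length R", call. = FALSE)
  if (any(!is.finite(log_firing)) || any(!is.finite(alpha)))
    stop("NaN or infinite values in view_activation inputs", call. = FALSE)
  u <- if (domain == "log") alpha * log_firing else alpha * exp(log_firing)
  softmax_vec(u)
}

#' Fuse per-view rule activations
#'
#' The global rule activation is the \eqn{\beta}-weighted convex combination
#' of the per-view simplex activations:
#' \eqn{f_{fused} = \sum_v \beta^{(v)} f^{(v)}}. Being a convex combination of
#' simplex points, the result is again on the simplex.
#'
#' @param per_view list of \code{V} numeric simplex vectors, all of length
#'   \code{R}.
#' @param weights a [view_weights()] with \code{V} components.
#' @return Fused simplex vector of length \code{R}.
#' @export
fuse_views <- function(per_view, weights) {
  stopifnot(inherits(weights, "view_weights"), is.list(per_view))
  if (length(per_view) != length(weights$beta))
    stop("number of activation vectors must match number of view weights", call. = FALSE)
  R <- unique(vapply(per_view, length, integer(1)))
  if (length(R) != 1L)
    stop("all views must share the same number of rules R", call. = FALSE)
  f <- numeric(R)
  for (v in seq_along(per_view)) f <- f + weights$beta[v] * per_view[[v]]
  f
}
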