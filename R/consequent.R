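#' First-order TSK consequent bank
#'
#' Each rule carries a first-order (linear) consequent mapping the
#' concatenation of all scaled view features to one score per class:
#' \eqn{y_r(x) = x^\top A_r + b_r}. Class scores of the full system are the
#' fused-activation-weighted combination of the per-rule outputs.
#'
#' @param A numeric array \code{[R x D_total x C]} of slopes (for binary or
#'   multi-class, \code{C >= 1}); a \code{[R x D_total]} matrix is promoted to
#'   \code{C = 1}.
#' @param b numeric matrix \code{[R x C]} of intercepts; a length-\code{R}
#'   vector is promoted to one column.
#' @return Object of class \code{"consequent_bank"}.
#' @export
consequent_bank <- function(A, b) {
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1L))
  if (!is.array(A) || length(dim(A)) != 3L)
    stop("A must be an [R x D x C] array", call. = FALSE)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1L)
  if (nrow(b) != dim(A)[1L] || ncol(b) != dim(A)[3L])
    stop("b must be [R x C] matching A", call. = FALSE)
  stop_if_not_finite(A, "A"); stop_if_not_finite(b, "b")
  structure(list(A = A, b = b,
                 n_rules = dim(A)[1L], n_features = dim(A)[2L], n_classes = dim(A)[3L]),
            class = "consequent_bank")
}

#' Per-rule consequent outputs for one input
#'
#' @param x_concat numeric vector of length \code{D_total}: the concatenation
#'   of all scaled per-view features.
#' @param bank a [consequent_bank()].
#' @return Numeric matrix \code{[R x C]}; row \code{r} is
#'   \eqn{x^\top A_r + b_r}.
#' @export
rule_outputs <- function(x_concat, bank) {
  stopifnot(inherits(bank, "consequent_bank"))
  if (length(x_concat) != bank$n_features)
    stop(sprintf("x_concat has length %d, consequents expect %d",
                 length(x_concat), bank$n_features), call. = FALSE)
  out <- matrix(0, bank$n_rules, bank$n_classes)
  for (cc in seq_len(bank$n_classes))
    out[, cc] <- bank$A[, , cc, drop = FALSE][, , 1L] %*% x_concat + bank$b[, cc]
  out
}

#' Combine rule outputs under a fused activation
#'
#' The system's class scores are the activation-weighted sum of per-rule
#' outputs, \eqn{score_c = \sum_r f_r\, y_{r,c}} — the defuzzification step of
#' a normalized TSK system, with the fused multi-view activation standing in
#' for the classic normalized firing.
#'
#' @param f_fused simplex vector of length \code{R}.
#' @param rule_out numeric matrix \code{[R x C]} from [rule_outputs()].
#' @return Numeric class-score vector of length \code{C}; its
#'   \code{which.max} is the predicted class.
#' @export
combine_rules <- function(f_fused, rule_out) {
  rule_out <- as.matrix(rule_out)
  if (length(f_fused) != nrow(rule_out))
    stop("f_fused length must equal nrow(rule_out)", call. = FALSE)
  drop(crossprod(rule_out, f_fused))
}

#' Extract one fuzzy rule in human-readable IF-THEN form
#'
#' Renders rule \code{r} of view \code{view} of a fitted model as text:
#' each feature's fuzzy set with its (shifted) center and width, followed by
#' the rule's linear consequent. Numeric parameters are printed at 6
#' significant digits so the text round-trips to the stored values at printed
#' precision.
#'
#' @param model a fitted [mvtsk()] model.
#' @param view view index in \code{1..V}.
#' @param r rule index in \code{1..R}.
#' @return A character scalar (the rule text), invisibly carrying the numeric
#'   parameters as attribute \code{"params"}.
#' @export
extract_rule <- function(model, view, r) {
  stopifnot(inherits(model, "mvtsk"))
  V <- length(model$params$views)
  if (view < 1 || view > V) stop("view index out of range", call. = FALSE)
  pv <- model$params$views[[view]]
  R <- ncol(pv$centers)
  if (r < 1 || r > R) stop("rule index out of range", call. = FALSE)
  D <- nrow(pv$centers)
  ctr <- pv$centers[, r] + pv$offsets[, r]
  sig <- pv$sigmas[, r]
  ante <- vapply(seq_len(D), function(d) {
    sprintf("x%d is A_%d,%d (centered at %.6g, width %.6g)", d, d, r, ctr[d], sig[d])
  }, character(1))
  # consequent slopes for this view's slice of the concatenated input
  off <- model$view_offsets[view]
  Dtot <- dim(model$params$A)[2L]
  C <- dim(model$params$A)[3L]
  cons <- vapply(seq_len(C), function(cc) {
    a <- model$params$A[r, , cc]
    terms <- paste(sprintf("%.6g*x%d", a[off + seq_len(D)], seq_len(D)), collapse = " + ")
    sprintf("y_%d[class %d] = %s + %.6g", r, cc, terms, model$params$b[r, cc])
  }, character(1))
  txt <- paste0("IF ", paste(ante, collapse = " AND "), "\nTHEN ",
                paste(cons, collapse = "; "))
  attr(txt, "params") <- list(centers = ctr, sigmas = sig,
                              slopes = model$params$A[r, off + seq_len(D), , drop = TRUE],
                              intercepts = model$params$b[r, ])
  invisible(txt)
}

#' Extract the complete rule base of a fitted model
#'
#' @param model a fitted [mvtsk()] model.
#' @return A character matrix \code{[R x V]} of rule texts; entry
#'   \code{[r, v]} is [extract_rule()]\code{(model, v, r)}.
#' @export
extract_rules <- function(model) {
  stopifnot(inherits(model, "mvtsk"))
  V <- length(model$params$views)
  R <- ncol(model$params$views[[1L]]$centers)
  out <- matrix("", R, V, dimnames = list(paste0("rule", seq_len(R)),
                                          paste0("view", seq_len(V))))
  for (v in seq_len(V)) for (r in seq_len(R)) out[r, v] <- extract_rule(model, v, r)
  out
}
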