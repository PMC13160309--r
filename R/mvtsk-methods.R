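#' Predict from a fitted multi-view TSK fuzzy classifier
#'
#' Applies the zero-shift and the scalers fitted on the training data, runs
#' the forward pass, and returns predictions on the requested scale.
#'
#' @param object a fitted [mvtsk()] model.
#' @param newdata list of per-view numeric matrices (row-aligned), or a
#'   \code{multiview_dataset}.
#' @param type \code{"class"} (default) returns predicted labels,
#'   \code{"prob"} the softmax class probabilities \code{[N x C]},
#'   \code{"score"} the raw class scores, \code{"activation"} the fused rule
#'   activations \code{[N x R]}.
#' @param ... unused.
#' @export
predict.mvtsk <- function(object, newdata,
                          type = c("class", "prob", "score", "activation"), ...) {
  type <- match.arg(type)
  Xs <- prepare_views(object, newdata)
  fw <- mvtsk_forward(object$params, Xs, object$struct, keep_cache = FALSE)
  switch(type,
    class = factor(object$classes[max.col(fw$probs, ties.method = "first")],
                   levels = object$classes),
    prob = structure(fw$probs, dimnames = list(NULL, object$classes)),
    score = structure(fw$scores, dimnames = list(NULL, object$classes)),
    activation = fw$fused)
}

# Apply stored preprocessing to new per-view matrices.
prepare_views <- function(object, newdata) {
  if (inherits(newdata, "multiview_dataset")) newdata <- newdata$views
  stopifnot(is.list(newdata), length(newdata) == object$struct$V)
  Xs <- vector("list", object$struct$V)
  for (v in seq_along(Xs)) {
    Xv <- shift_zeros(as.matrix(newdata[[v]]))
    if (object$scale != "none") Xv <- apply_scaler(object$scalers[[v]], Xv)
    if (ncol(Xv) != object$struct$dims[v])
      stop(sprintf("view %d has %d features, model expects %d",
                   v, ncol(Xv), object$struct$dims[v]), call. = FALSE)
    Xs[[v]] <- Xv
  }
  Xs
}

#' @export
print.mvtsk <- function(x, ...) {
  cat("Multi-view TSK fuzzy classifier\n")
  cat(sprintf("  variant: %s | rules: %d | views: %d (dims %s) | classes: %d\n",
              x$variant, x$n_rules, x$struct$V,
              paste(x$struct$dims, collapse = ", "), x$struct$C))
  cat(sprintf("  trained %d epochs (best epoch %d, monitored loss %.6f)\n",
              x$stopped_epoch, x$best_epoch,
              if (x$best_epoch > 0) x$history[x$best_epoch] else NA_real_))
  beta <- softmax_vec(x$params$view_logits)
  cat("  view weights beta:", paste(sprintf("%.4f", beta), collapse = " "), "\n")
  invisible(x)
}

#' Summarize a fitted multi-view TSK classifier
#'
#' Reports the architecture, the learned view weights, rule-usage
#' diagnostics per view (attention entropy on the uniform-input mean is not
#' meaningful without data, so entropies are reported when training views are
#' supplied via \code{data}), and the distribution of antecedent parameters.
#'
#' @param object a fitted [mvtsk()] model.
#' @param data optional list of per-view matrices (e.g. the training views)
#'   on which to compute mean attention weights and rule-usage statistics.
#' @param ... unused.
#' @export
summary.mvtsk <- function(object, data = NULL, ...) {
  beta <- softmax_vec(object$params$view_logits)
  fam <- lapply(c(center = "centers", sigma = "sigmas", offset = "offsets"),
                function(f) {
                  vals <- unlist(lapply(object$params$views, `[[`, f))
                  param_stats(vals, family = sub("s$", "", f))
                })
  usage <- NULL
  if (!is.null(data)) {
    usage <- lapply(seq_len(object$struct$V), function(v) {
      w <- mean_attention_over_samples(object, data, v)
      rule_usage(w, k = min(5L, object$n_rules))
    })
  }
  structure(list(model = object, beta = beta, param_families = fam,
                 rule_usage = usage),
            class = "summary.mvtsk")
}

#' @export
print.summary.mvtsk <- function(x, ...) {
  print(x$model)
  cat("\nAntecedent parameter families (mean, population sd):\n")
  for (nm in names(x$param_families)) {
    ps <- x$param_families[[nm]]
    cat(sprintf("  %-7s mu = %8.4f  sigma = %.4f\n", nm, ps$mean, ps$sd))
  }
  if (!is.null(x$rule_usage)) {
    cat("\nRule usage per view (entropy / normalized / effective / top-5):\n")
    for (v in seq_along(x$rule_usage)) {
      u <- x$rule_usage[[v]]
      cat(sprintf("  view %d: H = %.4f  H/lnR = %.4f  eff = %.2f  top%d = %.2f%%\n",
                  v, u$entropy, u$normalized_entropy, u$effective_rules,
                  u$k, 100 * u$top_k_contribution))
    }
  }
  invisible(x)
}

#' Coefficients of a fitted multi-view TSK classifier
#'
#' @param object a fitted [mvtsk()] model.
#' @param ... unused.
#' @return A list with per-view antecedent parameter matrices
#'   (\code{centers}, \code{offsets}, \code{sigmas}), the view weights
#'   \code{beta}, and the consequent \code{A} (slopes, \code{[R x D_total x C]})
#'   and \code{b} (intercepts).
#' @export
coef.mvtsk <- function(object, ...) {
  list(views = lapply(object$params$views,
                      function(p) p[c("centers", "offsets", "sigmas")]),
       beta = softmax_vec(object$params$view_logits),
       A = object$params$A, b = object$params$b)
}

#' Plot the training history of a fitted model
#'
#' Draws the monitored loss per epoch and marks the best (restored) epoch.
#'
#' @param x a fitted [mvtsk()] model.
#' @param ... passed to \code{plot.default}.
#' @export
plot.mvtsk <- function(x, ...) {
  plot(seq_along(x$history), x$history, type = "l",
       xlab = "epoch", ylab = "monitored loss",
       main = sprintf("mvtsk training (%s variant)", x$variant), ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
fitted.mvtsk <- function(object, ...) {
  stop("mvtsk does not retain its training data; call predict(object, views)",
       call. = FALSE)
}
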