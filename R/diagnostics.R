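#' Shannon entropy of rule attention weights
#'
#' \eqn{H = -\sum_r w_r \ln w_r} in nats, with \eqn{0 \ln 0 := 0}. Weights
#' must lie on the simplex; sums within \code{1e-6} of 1 are renormalized,
#' anything further off is an error.
#'
#' @param weights non-negative numeric vector summing to 1 (within 1e-6).
#' @return Entropy in nats, in \code{[0, ln R]}.
#' @export
attention_entropy <- function(weights) {
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  s <- sum(weights)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("weights sum to %.8f, not a simplex vector", s), call. = FALSE)
  w <- weights / s
  w <- w[w > 0]
  -sum(w * log(w))
}

#' Rule-usage statistics of a mean attention-weight vector
#'
#' Summarizes how uniformly a view uses its rule base. From the
#' sample-averaged attention weights it reports the Shannon entropy \code{H}
#' (nats), the normalized entropy \code{H / ln R}, the effective number of
#' rules \code{exp(H)} (the perplexity of the weight distribution), the
#' proportion of active rules \code{exp(H) / R}, and the summed weight of the
#' \code{k} largest rules (top-k contribution).
#'
#' @param mean_weights simplex vector of length \code{R}: attention weights
#'   averaged over samples (see [mean_attention_over_samples()]).
#' @param k how many top rules the contribution statistic sums (default 5).
#' @return Object of class \code{"rule_usage"}: list with \code{entropy},
#'   \code{normalized_entropy}, \code{effective_rules},
#'   \code{proportion_active}, \code{top_k_contribution}, \code{top_k_rules}
#'   (indices), \code{k} and \code{n_rules}.
#' @export
rule_usage <- function(mean_weights, k = 5L) {
  R <- length(mean_weights)
  k <- as.integer(k)
  if (k < 1L || k > R) stop("k must be in 1..R", call. = FALSE)
  H <- attention_entropy(mean_weights)
  ord <- order(mean_weights, decreasing = TRUE)
  structure(
    c(rule_usage_from_entropy(H, R),
      list(mean_weights = mean_weights,
           top_k_contribution = sum(mean_weights[ord[seq_len(k)]]) / sum(mean_weights),
           top_k_rules = ord[seq_len(k)],
           k = k)),
    class = "rule_usage")
}

#' Entropy-derived rule-usage statistics
#'
#' The deterministic core of [rule_usage()]: given an entropy \code{H} (nats)
#' of a rule-weight distribution over \code{R} rules, returns
#' \code{normalized_entropy = H / ln R}, \code{effective_rules = exp(H)}
#' (perplexity), and \code{proportion_active = exp(H) / R}. Useful for
#' checking published entropy tables for internal consistency.
#'
#' @param H entropy in nats, \code{0 <= H <= ln R}.
#' @param R number of rules.
#' @export
rule_usage_from_entropy <- function(H, R) {
  stopifnot(is.finite(H), H >= 0, R >= 1)
  if (H > log(R) + 1e-9)
    stop(sprintf("entropy %.4f exceeds ln(R) = %.4f", H, log(R)), call. = FALSE)
  list(entropy = H,
       normalized_entropy = H / log(R),
       effective_rules = exp(H),
       proportion_active = exp(H) / R,
       n_rules = as.integer(R))
}

#' @export
print.rule_usage <- function(x, ...) {
  cat(sprintf("Rule usage over %d rules: H = %.4f nats (normalized %.4f)\n",
              x$n_rules, x$entropy, x$normalized_entropy))
  cat(sprintf("  effective rules %.2f (%.2f%% active); top-%d contribution %.2f%%\n",
              x$effective_rules, 100 * x$proportion_active, x$k,
              100 * x$top_k_contribution))
  invisible(x)
}

#' Location and spread of an antecedent parameter family
#'
#' Mean and population (1/N) standard deviation, plus quartiles by linear
#' interpolation, of one family of antecedent parameters (centers, sigmas,
#' or offsets) — the statistics used to judge the stability of the
#' deformable antecedents after training.
#'
#' @param values numeric vector (non-empty) of parameter values.
#' @param family one of \code{"center"}, \code{"sigma"}, \code{"offset"}.
#' @return List with \code{family}, \code{mean}, \code{sd} (population),
#'   and \code{quartiles} (0\%, 25\%, 50\%, 75\%, 100\%).
#' @export
param_stats <- function(values, family = c("center", "sigma", "offset")) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (!length(values)) stop("empty parameter collection", call. = FALSE)
  mu <- mean(values)
  list(family = family,
       mean = mu,
       sd = sqrt(mean((values - mu)^2)),       # 1/N convention
       quartiles = stats::quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1),
                                   type = 7, names = TRUE))
}

#' Sample-averaged rule attention weights of one view
#'
#' Runs the model's forward pass over a dataset and averages the per-sample
#' rule attention weights of the requested view. The mean of simplex vectors
#' is itself on the simplex. For variants without an attention block the
#' weights are uniform by construction.
#'
#' @param model a fitted [mvtsk()] model.
#' @param data list of per-view matrices or a \code{multiview_dataset}.
#' @param view view index.
#' @return Simplex vector of length \code{R}.
#' @export
mean_attention_over_samples <- function(model, data, view) {
  stopifnot(inherits(model, "mvtsk"))
  Xs <- prepare_views(model, data)
  if (nrow(Xs[[1L]]) == 0L) stop("empty dataset", call. = FALSE)
  if (view < 1 || view > model$struct$V)
    stop("view index out of range", call. = FALSE)
  fw <- mvtsk_forward(model$params, Xs, model$struct, keep_cache = FALSE)
  a <- fw$alphas[[view]]
  a <- a / rowSums(a)          # all-ones path of attention-free variants
  colMeans(a)
}
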