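#' Stratified train/test split
#'
#' Splits sample indices so that each class keeps (to within rounding) the
#' requested training fraction; within each class the training rows are
#' drawn uniformly at random, deterministically for a given seed. Each class
#' contributes at least one row to each side.
#'
#' @param labels vector of class labels, length \code{N}; every class must
#'   have at least 2 members.
#' @param fraction training fraction in \code{(0, 1)} (default 0.8).
#' @param seed integer seed.
#' @return List with integer index vectors \code{train} and \code{test}
#'   (disjoint, jointly exhaustive).
#' @export
split_stratified <- function(labels, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  y <- as.factor(labels)
  tab <- table(y)
  if (any(tab < 2L))
    stop(sprintf("class '%s' has fewer than 2 members; cannot stratify",
                 names(tab)[which(tab < 2L)[1L]]), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- round(fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)   # both sides non-empty
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' One-sample t-test of run accuracies against a fixed benchmark
#'
#' Two-sided one-sample t-test of a vector of per-run accuracies against a
#' benchmark accuracy treated as a fixed constant (the usual situation when
#' a published baseline reports a mean without run-wise variance). Zero
#' variance across runs makes the statistic undefined; it is then reported
#' as \code{NA} with a warning rather than an error.
#'
#' @param accuracies numeric vector of per-run accuracies (length >= 2).
#' @param benchmark the fixed benchmark accuracy.
#' @return List with \code{mean}, \code{sd} (sample, n-1 denominator),
#'   \code{t}, \code{df}, \code{p_value}.
#' @export
protocol_ttest <- function(accuracies, benchmark) {
  stopifnot(length(accuracies) >= 2L, is.finite(benchmark))
  m <- mean(accuracies)
  s <- stats::sd(accuracies)
  if (s == 0) {
    warning("zero variance across runs; t statistic undefined")
    return(list(mean = m, sd = 0, t = NA_real_,
                df = length(accuracies) - 1L, p_value = NA_real_))
  }
  tt <- stats::t.test(accuracies, mu = benchmark, alternative = "two.sided")
  list(mean = m, sd = s, t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value)
}

#' Multi-run train/evaluate protocol
#'
#' Repeats the full pipeline — stratified 80/20 split, model fit on the
#' training rows (scalers fitted on those rows only), accuracy on the held
#' out rows — for \code{n_runs} seeded runs (run \code{k} uses seed
#' \code{seed + k - 1} for both split and initialization) and reports the
#' accuracy distribution, optionally with a one-sample t-test against a
#' fixed benchmark accuracy.
#'
#' @param views list of per-view matrices or a \code{multiview_dataset}.
#' @param labels labels (ignored for a \code{multiview_dataset}).
#' @param n_runs number of independent runs (default 20).
#' @param benchmark optional fixed benchmark accuracy for the t-test.
#' @param train_fraction training fraction (default 0.8).
#' @param seed base seed.
#' @param ... passed on to [mvtsk()] (e.g. \code{n_rules}, \code{variant},
#'   \code{control}).
#' @return Object of class \code{"mvtsk_protocol"}: list with
#'   \code{accuracies}, \code{mean}, \code{sd} (n-1), \code{ttest} (or
#'   \code{NULL}), \code{histories}, and the per-run seeds.
#' @export
run_protocol <- function(views, labels = NULL, n_runs = 20L, benchmark = NULL,
                         train_fraction = 0.8, seed = 1L, ...) {
  stopifnot(n_runs >= 2L)
  if (inherits(views, "multiview_dataset")) {
    labels <- views$labels
    views <- views$views
  }
  views <- lapply(views, as.matrix)
  seeds <- as.integer(seed) + seq_len(n_runs) - 1L
  acc <- numeric(n_runs)
  histories <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    sp <- split_stratified(labels, fraction = train_fraction, seed = seeds[k])
    tr_views <- lapply(views, function(m) m[sp$train, , drop = FALSE])
    te_views <- lapply(views, function(m) m[sp$test, , drop = FALSE])
    fit <- mvtsk(tr_views, labels[sp$train], seed = seeds[k], ...)
    pred <- predict(fit, te_views)
    acc[k] <- mean(as.character(pred) == as.character(labels[sp$test]))
    histories[[k]] <- fit$history
  }
  tt <- if (!is.null(benchmark)) protocol_ttest(acc, benchmark) else NULL
  structure(list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
                 ttest = tt, benchmark = benchmark,
                 histories = histories, seeds = seeds),
            class = "mvtsk_protocol")
}

#' @export
print.mvtsk_protocol <- function(x, ...) {
  cat(sprintf("Protocol over %d runs: accuracy %.4f +/- %.4f\n",
              length(x$accuracies), x$mean, x$sd))
  if (!is.null(x$ttest)) {
    cat(sprintf("  one-sample t vs benchmark %.4f: t = %s, df = %d, p = %s\n",
                x$benchmark,
                if (is.na(x$ttest$t)) "undefined" else sprintf("%.4f", x$ttest$t),
                x$ttest$df,
                if (is.na(x$ttest$p_value)) "undefined" else
                  format.pval(x$ttest$p_value, digits = 4)))
  }
  invisible(x)
}
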