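#' Rule bank of deformable Gaussian membership functions
#'
#' A rule bank holds the antecedent parameters of one view of a TSK fuzzy
#' system: for each of \code{R} rules and \code{D} features a Gaussian
#' membership function with center \eqn{c_{d,r}}, trainable center offset
#' \eqn{\Delta c_{d,r}} (the "deformation"), and width \eqn{\sigma_{d,r} > 0}.
#' The effective center of rule \code{r} in feature \code{d} is
#' \eqn{c_{d,r} + \Delta c_{d,r}}.
#'
#' @param centers numeric matrix \code{[D x R]} of membership centers, in
#'   (post-scaling) feature units.
#' @param offsets numeric matrix \code{[D x R]} of trainable center offsets;
#'   all-zero offsets recover the standard Gaussian membership function.
#' @param sigmas numeric matrix \code{[D x R]} of strictly positive widths.
#' @return An object of class \code{"rule_bank"}: a list with elements
#'   \code{centers}, \code{offsets}, \code{sigmas}, \code{n_features} (D) and
#'   \code{n_rules} (R).
#' @examples
#' rb <- rule_bank(centers = matrix(0, 2, 3), offsets = matrix(0, 2, 3),
#'                 sigmas = matrix(1, 2, 3))
#' membership(0, rb, d = 1, r = 1)  # at the center: 1
#' @export
rule_bank <- function(centers, offsets = NULL, sigmas = NULL) {
  centers <- as.matrix(centers)
  if (is.null(offsets)) offsets <- matrix(0, nrow(centers), ncol(centers))
  if (is.null(sigmas)) sigmas <- matrix(1, nrow(centers), ncol(centers))
  offsets <- as.matrix(offsets)
  sigmas <- as.matrix(sigmas)
  if (!identical(dim(centers), dim(offsets)) || !identical(dim(centers), dim(sigmas)))
    stop("centers, offsets and sigmas must share shape [D x R]", call. = FALSE)
  stop_if_not_finite(centers, "centers")
  stop_if_not_finite(offsets, "offsets")
  stop_if_not_finite(sigmas, "sigmas")
  if (any(sigmas <= 0)) stop("all sigmas must be strictly positive", call. = FALSE)
  structure(
    list(centers = centers, offsets = offsets, sigmas = sigmas,
         n_features = nrow(centers), n_rules = ncol(centers)),
    class = "rule_bank"
  )
}

#' @export
print.rule_bank <- function(x, ...) {
  cat(sprintf("Rule bank: %d rules over %d features\n", x$n_rules, x$n_features))
  cat(sprintf("  deformation: %s (max |offset| = %.4g)\n",
              if (all(x$offsets == 0)) "none (standard Gaussian memberships)" else "active",
              max(abs(x$offsets))))
  cat(sprintf("  sigma range: [%.4g, %.4g]\n", min(x$sigmas), max(x$sigmas)))
  invisible(x)
}

#' Deformable Gaussian membership degree
#'
#' Evaluates the membership of a scalar feature value in one rule's fuzzy set:
#' \deqn{\mu_{d,r}(x) = \exp\left(-\frac{(x - (c_{d,r} + \Delta c_{d,r}))^2}
#'   {2\sigma_{d,r}^2}\right)}
#' The value is 1 exactly when \code{x_d} sits at the shifted center and decays
#' monotonically with distance from it.
#'
#' @param x_d finite numeric scalar, the feature value.
#' @param bank a [rule_bank()].
#' @param d feature index in \code{1..D}.
#' @param r rule index in \code{1..R}.
#' @return A numeric scalar in \code{(0, 1]}.
#' @export
membership <- function(x_d, bank, d, r) {
  stopifnot(inherits(bank, "rule_bank"))
  if (d < 1 || d > bank$n_features || r < 1 || r > bank$n_rules)
    stop("feature or rule index out of range", call. = FALSE)
  if (!is.finite(x_d)) stop("x_d must be finite", call. = FALSE)
  m <- bank$centers[d, r] + bank$offsets[d, r]
  s <- bank$sigmas[d, r]
  exp(-(x_d - m)^2 / (2 * s^2))
}

#' Log-firing strength of every rule for one input vector
#'
#' The firing strength of a TSK rule is the product over features of its
#' membership degrees; in high dimension that product underflows, so all
#' antecedent computation here is carried in log space:
#' \deqn{\ln a_r(x) = \sum_{d=1}^{D}
#'   -\frac{(x_d - (c_{d,r} + \Delta c_{d,r}))^2}{2\sigma_{d,r}^2}}
#' \code{exp(log_firing(x, bank))} equals the product of per-feature
#' memberships (never materialized for large D).
#'
#' @param x finite numeric vector of length \code{D}.
#' @param bank a [rule_bank()].
#' @return Numeric vector of length \code{R}; all components are \code{<= 0},
#'   with 0 attained exactly at a rule's shifted center.
#' @export
log_firing <- function(x, bank) {
  stopifnot(inherits(bank, "rule_bank"))
  if (length(x) != bank$n_features)
    stop(sprintf("x has length %d but the bank expects %d features",
                 length(x), bank$n_features), call. = FALSE)
  stop_if_not_finite(x, "x")
  drop(log_firing_batch(matrix(x, nrow = 1L), bank$centers + bank$offsets, bank$sigmas))
}

# Batched log-firing: X [B x D], M = centers + offsets [D x R], S sigmas [D x R].
# Z_br = -sum_d (x_bd - m_dr)^2 / (2 s_dr^2), expanded so the whole batch is
# three matrix products.
log_firing_batch <- function(X, M, S) {
  W <- 1 / (2 * S^2)                       # [D x R]
  Z <- -(X^2 %*% W - 2 * (X %*% (M * W)) + rep_row(colSums(M^2 * W), nrow(X)))
  # guard tiny positive round-off at the exact center
  Z[Z > 0] <- 0
  Z
}

#' Initialize a rule bank from training data
#'
#' Centers come from the data (either \code{R} distinct training rows or the
#' centroids of a k-means partition); offsets start at exactly zero, so the
#' untrained model is a standard-membership TSK system; sigmas start at 1,
#' the scale the widths typically stay near after training on standardized
#' features.
#'
#' @param X_train numeric matrix \code{[N x D]} of (already scaled) training
#'   features.
#' @param R number of rules.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param strategy \code{"sample"} draws centers from training rows without
#'   replacement; \code{"kmeans"} uses \code{stats::kmeans} centroids.
#' @return A [rule_bank()].
#' @export
init_rule_bank <- function(X_train, R, seed = 1L, strategy = c("sample", "kmeans")) {
  strategy <- match.arg(strategy)
  X_train <- as.matrix(X_train)
  N <- nrow(X_train); D <- ncol(X_train)
  if (R < 1) stop("R must be >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (strategy == "sample") {
    if (N < R)
      stop(sprintf("need at least R = %d training rows for strategy 'sample', got %d", R, N),
           call. = FALSE)
    centers <- t(X_train[sample.int(N, R), , drop = FALSE])
  } else {
    km <- stats::kmeans(X_train, centers = min(R, N), nstart = 3L, iter.max = 50L)
    cent <- km$centers
    if (nrow(cent) < R) cent <- cent[rep_len(seq_len(nrow(cent)), R), , drop = FALSE]
    centers <- t(cent)
  }
  rule_bank(centers = centers,
            offsets = matrix(0, D, R),
            sigmas = matrix(1, D, R))
}

# Save/restore the global RNG state so seeded initializers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
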