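#' Generate synthetic class-conditional multi-view data
#'
#' Emulates the structure the classifier is designed for: samples carry a
#' latent class-conditional signal observed through several heterogeneous
#' views. Labels are assigned round-robin (so classes are balanced to within
#' one sample and stratified splitting is always valid); latent vectors are
#' drawn from spherical Gaussians whose class centers sit at mutual distance
#' \code{separation} (in units of the unit latent standard deviation); each
#' view is its own random linear map of the latent signal plus independent
#' Gaussian noise. Redundant views — corrupted copies of an existing view —
#' model the cross-view redundancy that makes rule re-weighting worthwhile.
#'
#' \code{separation = 0} is the no-signal control: all class-conditional
#' distributions coincide and no classifier can beat chance in expectation.
#'
#' @param n_samples number of samples (default 400).
#' @param n_views number of independently mapped views (default 2).
#' @param dims integer vector of per-view feature dimensions (recycled to
#'   \code{n_views}; default \code{c(8, 6)}).
#' @param n_classes number of classes (default 3).
#' @param separation pairwise distance between latent class centers, in
#'   latent standard deviations (default 4).
#' @param noise_sd standard deviation of the additive per-view observation
#'   noise (default 0.1).
#' @param latent_dim dimension of the latent space (raised to
#'   \code{n_classes} if smaller, so centers can be mutually equidistant).
#' @param redundant_views optional list of \code{list(source =, corruption_sd =)}
#'   entries; each appends a corrupted copy of view \code{source}.
#' @param nonlinear if \code{TRUE}, passes each view through \code{tanh}
#'   after the linear map.
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @return A list with \code{dataset} (a [multiview_dataset()]) and
#'   \code{truth}: the latent class centers \code{[C x latent_dim]}, the
#'   per-view linear maps, and the latent draws themselves.
#' @examples
#' g <- generate_multiview(n_samples = 60, separation = 6, seed = 1)
#' table(g$dataset$labels)
#' @export
generate_multiview <- function(n_samples = 400L, n_views = 2L,
                               dims = c(8L, 6L), n_classes = 3L,
                               separation = 4, noise_sd = 0.1,
                               latent_dim = 4L,
                               redundant_views = NULL,
                               nonlinear = FALSE, seed = 1L) {
  stopifnot(n_samples >= 1, n_views >= 1, n_classes >= 1,
            separation >= 0, noise_sd >= 0)
  dims <- rep_len(as.integer(dims), n_views)
  if (any(dims < 1)) stop("view dimensions must be positive", call. = FALSE)
  L <- max(as.integer(latent_dim), n_classes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  # round-robin labels: balanced to within one sample
  y <- rep_len(seq_len(n_classes) - 1L, n_samples)
  # mutually equidistant centers: scaled standard basis vectors
  centers <- diag(L)[seq_len(n_classes), , drop = FALSE] * separation / sqrt(2)
  Z <- centers[y + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n_samples * L), n_samples, L)

  maps <- vector("list", n_views)
  views <- vector("list", n_views)
  for (v in seq_len(n_views)) {
    P <- matrix(stats::rnorm(L * dims[v], sd = 1 / sqrt(L)), L, dims[v])
    Xv <- Z %*% P + matrix(stats::rnorm(n_samples * dims[v], sd = noise_sd),
                           n_samples, dims[v])
    if (nonlinear) Xv <- tanh(Xv)
    maps[[v]] <- P
    views[[v]] <- Xv
  }
  if (!is.null(redundant_views)) {
    for (rv in redundant_views) {
      src <- rv$source
      if (src < 1 || src > length(views))
        stop("redundant view source index out of range", call. = FALSE)
      corr <- rv$corruption_sd %||% 0.5
      views[[length(views) + 1L]] <-
        views[[src]] + matrix(stats::rnorm(length(views[[src]]), sd = corr),
                              nrow(views[[src]]))
    }
  }
  list(dataset = multiview_dataset(views, y),
       truth = list(latent_centers = centers, maps = maps, latent = Z))
}

#' Tiny fixed two-view dataset for documentation and bit-exact tests
#'
#' Twelve samples, two views of 2 and 3 features, two balanced classes. The
#' values are hard-coded literals, so every run and every platform sees the
#' identical dataset.
#'
#' @return A list with \code{views} (list of a \code{12 x 2} and a
#'   \code{12 x 3} matrix) and \code{labels} (integer \code{0/1}, 6 of each).
#' @export
worked_example <- function() {
  v1 <- matrix(c(
    -0.63, 0.18,  -0.84, 1.60,  0.33, -0.82,  0.49, 0.74,  0.58, -0.31,
     1.51, 0.39,
     2.62, 1.59,  2.92, 2.72,  2.41, 3.19,  3.14, 1.84,  2.21, 2.49,
     3.36, 2.75), ncol = 2, byrow = TRUE)
  v2 <- matrix(c(
     0.90, 0.10, -0.62,   1.21, -0.04,  0.17,   0.70,  0.58, -0.56,
     1.11,  0.24, -0.02,   0.76, -0.29, -0.31,   1.39,  0.45, -0.64,
    -1.21, 1.16,  1.87,  -0.74,  0.86,  2.17,  -1.26,  1.42,  2.33,
    -0.95,  0.74,  1.54,  -1.42,  1.02,  2.51,  -0.83,  1.30,  1.99),
    ncol = 3, byrow = TRUE)
  list(views = list(v1, v2),
       labels = rep(c(0L, 1L), each = 6L))
}
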