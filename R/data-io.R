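#' Construct a multi-view dataset
#'
#' Bundles row-aligned per-view feature matrices with a label vector. Labels
#' of any type are remapped to consecutive integer codes \code{0..C-1}; the
#' original values are recorded in \code{label_map}.
#'
#' @param views list of numeric matrices, all with the same number of rows.
#' @param labels vector of length \code{N} (factor, integer or character).
#' @param view_names optional character names for the views.
#' @return Object of class \code{"multiview_dataset"} with elements
#'   \code{views}, \code{labels} (integer \code{0..C-1}), \code{label_map}
#'   (original value for each code) and \code{view_names}.
#' @export
multiview_dataset <- function(views, labels, view_names = NULL) {
  stopifnot(is.list(views), length(views) >= 1L)
  views <- lapply(views, function(v) {
    m <- as.matrix(v)
    if (!is.numeric(m)) stop("non-numeric entries in a view matrix", call. = FALSE)
    m
  })
  n <- vapply(views, nrow, integer(1))
  if (length(unique(n)) != 1L)
    stop(sprintf("views are not row-aligned: row counts %s",
                 paste(n, collapse = ", ")), call. = FALSE)
  if (length(labels) != n[1L])
    stop("labels length must equal the number of rows", call. = FALSE)
  fac <- as.factor(labels)
  if (is.null(view_names)) view_names <- paste0("view_", seq_along(views))
  names(views) <- view_names
  structure(list(views = views,
                 labels = as.integer(fac) - 1L,
                 label_map = levels(fac),
                 view_names = view_names),
            class = "multiview_dataset")
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("Multi-view dataset: %d samples, %d views, %d classes\n",
              nrow(x$views[[1L]]), length(x$views), length(x$label_map)))
  for (v in seq_along(x$views))
    cat(sprintf("  %s: %d features\n", x$view_names[v], ncol(x$views[[v]])))
  invisible(x)
}

#' Load a multi-view dataset from disk
#'
#' The delimited layout is a directory holding one numeric CSV per view,
#' named \code{view_1.csv .. view_V.csv} (no header), plus \code{labels.csv}
#' with one label per row. MAT containers are a common distribution format
#' for these benchmarks but have no reader in this package's dependency set;
#' convert to the delimited layout (one matrix per view) to load them.
#'
#' @param path directory containing the view and label files.
#' @param format only \code{"delimited"} is supported.
#' @return A [multiview_dataset()].
#' @export
read_multiview <- function(path, format = c("delimited", "mat")) {
  format <- match.arg(format)
  if (format == "mat")
    stop("MAT containers are not supported; export each view matrix and the ",
         "label vector to the delimited layout (view_1.csv ... labels.csv) ",
         "and load with format = \"delimited\"", call. = FALSE)
  files <- sort(list.files(path, pattern = "^view_[0-9]+\\.(csv|tsv)$",
                           full.names = TRUE))
  if (!length(files))
    stop(sprintf("no view_*.csv files found in %s", path), call. = FALSE)
  # order numerically, not lexically
  idx <- as.integer(sub("^view_([0-9]+)\\..*$", "\\1", basename(files)))
  files <- files[order(idx)]
  views <- lapply(files, function(f) {
    sep <- if (grepl("\\.tsv$", f)) "\t" else ","
    m <- as.matrix(utils::read.table(f, sep = sep, header = FALSE))
    if (!is.numeric(m)) stop(sprintf("non-numeric entries in %s", f), call. = FALSE)
    dimnames(m) <- NULL
    m
  })
  lf <- file.path(path, "labels.csv")
  if (!file.exists(lf)) stop(sprintf("missing labels file %s", lf), call. = FALSE)
  labels <- utils::read.table(lf, header = FALSE)[[1L]]
  multiview_dataset(views, labels,
                    view_names = sub("\\.(csv|tsv)$", "", basename(files)))
}

#' Write a multi-view dataset to the delimited layout
#'
#' @param dataset a [multiview_dataset()].
#' @param path output directory (created if absent).
#' @return \code{path}, invisibly.
#' @export
write_multiview <- function(dataset, path) {
  stopifnot(inherits(dataset, "multiview_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (v in seq_along(dataset$views)) {
    utils::write.table(dataset$views[[v]],
                       file.path(path, sprintf("view_%d.csv", v)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(dataset$labels, file.path(path, "labels.csv"),
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Shift exact zeros by a negligible constant
#'
#' Feature matrices in these benchmarks often contain structural zeros that
#' destabilize later scaling; entries exactly equal to zero are replaced by
#' \code{epsilon}, all other entries are untouched. Idempotent for any
#' \code{epsilon != 0}.
#'
#' @param X numeric matrix or vector.
#' @param epsilon replacement value for exact zeros (default \code{1e-8}).
#' @export
shift_zeros <- function(X, epsilon = 1e-8) {
  stop_if_not_finite(X, "X")
  X[X == 0] <- epsilon
  X
}

#' Fit a per-column feature scaler on training rows
#'
#' \code{"minmax"} maps each training column's range to \code{[0, 1]};
#' \code{"standard"} centers on the training mean and divides by the
#' population (1/N) standard deviation. Constant columns map to all zeros
#' with a warning. The fitted statistics come from the supplied rows only;
#' applying the scaler to later (test) rows may produce values outside
#' \code{[0, 1]} — by design, no test statistic ever enters the state.
#'
#' @param X_train numeric training matrix (non-empty).
#' @param kind \code{"minmax"} or \code{"standard"}.
#' @return A scaler-state list understood by [apply_scaler()].
#' @export
fit_scaler <- function(X_train, kind = c("minmax", "standard")) {
  kind <- match.arg(kind)
  X_train <- as.matrix(X_train)
  if (nrow(X_train) == 0L) stop("empty training set", call. = FALSE)
  if (kind == "minmax") {
    lo <- apply(X_train, 2L, min)
    hi <- apply(X_train, 2L, max)
    const <- hi - lo == 0
    if (any(const))
      warning(sprintf("%d constant column(s) will map to 0", sum(const)))
    state <- list(kind = kind, lo = lo, span = ifelse(const, 1, hi - lo),
                  const = const)
  } else {
    mu <- colMeans(X_train)
    sd_pop <- sqrt(colMeans(sweep(X_train, 2L, mu)^2))   # 1/N convention
    const <- sd_pop == 0
    if (any(const))
      warning(sprintf("%d constant column(s) will map to 0", sum(const)))
    state <- list(kind = kind, mu = mu, sd = ifelse(const, 1, sd_pop),
                  const = const)
  }
  structure(state, class = "mvtsk_scaler")
}

#' Apply a fitted scaler to a matrix
#'
#' @param state a scaler from [fit_scaler()].
#' @param X numeric matrix with the same number of columns the scaler was
#'   fitted on.
#' @export
apply_scaler <- function(state, X) {
  stopifnot(inherits(state, "mvtsk_scaler"))
  X <- as.matrix(X)
  out <- if (state$kind == "minmax") {
    sweep(sweep(X, 2L, state$lo), 2L, state$span, "/")
  } else {
    sweep(sweep(X, 2L, state$mu), 2L, state$sd, "/")
  }
  if (any(state$const)) out[, state$const] <- 0
  out
}
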