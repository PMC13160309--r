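#' Save a fitted model to a JSON checkpoint
#'
#' The checkpoint is a flat key-value JSON object: every parameter array is
#' stored under a dotted path (\code{views.v1.centers},
#' \code{views.v1.attention.Wv.h1}, \code{A}, ...) as \code{\{dim, data\}},
#' alongside the model metadata (variant, dimensions, classes, scalers,
#' training history). Text-only and platform independent; numbers are
#' written at maximal JSON precision (15 significant digits).
#'
#' @param model a fitted [mvtsk()] model.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_mvtsk <- function(model, path) {
  stopifnot(inherits(model, "mvtsk"))
  flat <- list()
  add <- function(key, x) {
    flat[[key]] <<- list(dim = dim(x) %||% length(x), data = as.numeric(x))
  }
  for (v in names(model$params$views)) {
    p <- model$params$views[[v]]
    add(paste0("views.", v, ".centers"), p$centers)
    add(paste0("views.", v, ".offsets"), p$offsets)
    add(paste0("views.", v, ".sigmas"), p$sigmas)
    if (!is.null(p$attention)) {
      att <- p$attention
      for (i in seq_len(att$n_heads)) {
        add(paste0("views.", v, ".attention.Wq.h", i), att$Wq[[i]])
        add(paste0("views.", v, ".attention.Wk.h", i), att$Wk[[i]])
        add(paste0("views.", v, ".attention.Wv.h", i), att$Wv[[i]])
      }
      add(paste0("views.", v, ".attention.Wo"), att$Wo)
      add(paste0("views.", v, ".attention.Wfc"), att$Wfc)
      add(paste0("views.", v, ".attention.bfc"), att$bfc)
    }
  }
  add("view_logits", model$params$view_logits)
  add("A", model$params$A)
  add("b", model$params$b)

  scalers <- lapply(model$scalers, function(s) {
    if (is.null(s)) return(NULL)
    c(unclass(s), list(const = as.logical(s$const)))
  })
  meta <- list(package = "fuzzyview", format = 1L,
               variant = model$variant, n_rules = model$n_rules,
               struct = model$struct, classes = model$classes,
               scale = model$scale, scalers = scalers,
               view_offsets = model$view_offsets,
               history = model$history, best_epoch = model$best_epoch,
               stopped_epoch = model$stopped_epoch, seed = model$seed,
               n_heads = if (model$struct$attention_on)
                 vapply(model$params$views, function(p) p$attention$n_heads,
                        integer(1)) else NA)
  jsonlite::write_json(list(meta = meta, params = flat), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a fitted model from a JSON checkpoint
#'
#' @param path file written by [write_mvtsk()].
#' @return An [mvtsk()] model object equivalent to the one saved.
#' @export
read_mvtsk <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  meta <- ck$meta
  flat <- ck$params
  get_arr <- function(key) {
    e <- flat[[key]]
    if (is.null(e)) stop(sprintf("checkpoint is missing '%s'", key), call. = FALSE)
    if (length(e$dim) > 1L) array(e$data, dim = e$dim) else as.numeric(e$data)
  }
  struct <- meta$struct
  struct$dims <- as.integer(struct$dims)
  V <- struct$V
  pv <- vector("list", V)
  names(pv) <- paste0("v", seq_len(V))
  for (v in seq_len(V)) {
    nm <- names(pv)[v]
    att <- NULL
    if (isTRUE(struct$attention_on)) {
      H <- as.integer(unlist(meta$n_heads))[v]
      hn <- paste0("h", seq_len(H))
      grab_heads <- function(which)
        stats::setNames(lapply(seq_len(H), function(i)
          get_arr(paste0("views.", nm, ".attention.", which, ".h", i))), hn)
      att <- structure(
        list(Wq = grab_heads("Wq"), Wk = grab_heads("Wk"), Wv = grab_heads("Wv"),
             Wo = get_arr(paste0("views.", nm, ".attention.Wo")),
             Wfc = get_arr(paste0("views.", nm, ".attention.Wfc")),
             bfc = get_arr(paste0("views.", nm, ".attention.bfc")),
             n_heads = H, D = struct$dims[v], R = struct$R),
        class = "attention_params")
    }
    pv[[v]] <- list(centers = get_arr(paste0("views.", nm, ".centers")),
                    offsets = get_arr(paste0("views.", nm, ".offsets")),
                    sigmas = get_arr(paste0("views.", nm, ".sigmas")),
                    attention = att)
  }
  scalers <- lapply(meta$scalers, function(s) {
    if (is.null(s) || length(s) == 0L) return(NULL)
    structure(s, class = "mvtsk_scaler")
  })
  structure(
    list(params = list(views = pv,
                       view_logits = get_arr("view_logits"),
                       A = get_arr("A"),
                       b = {bm <- get_arr("b"); if (is.null(dim(bm))) matrix(bm, ncol = 1L) else bm}),
         struct = struct, history = as.numeric(meta$history),
         best_epoch = meta$best_epoch, stopped_epoch = meta$stopped_epoch,
         classes = as.character(meta$classes), variant = meta$variant,
         n_rules = as.integer(meta$n_rules),
         scalers = scalers, scale = meta$scale,
         view_offsets = as.integer(meta$view_offsets),
         seed = meta$seed, control = NULL, call = NULL),
    class = "mvtsk")
}
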