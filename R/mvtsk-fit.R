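#' Training control parameters
#'
#' Defaults follow the training protocol the model is designed around:
#' AdamW with learning rate 5e-4 and weight decay 1e-8, minibatches of 8,
#' at most 256 epochs, early stopping with patience 50.
#'
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of passes over the training data.
#' @param patience epochs without improvement of the monitored loss before
#'   stopping; best-loss parameters are restored.
#' @param validation_fraction fraction of the training data held out to
#'   monitor early stopping; 0 (default) monitors the training loss itself.
#' @param verbose print per-epoch loss.
#' @return A list of class \code{"mvtsk_control"}.
#' @export
mvtsk_control <- function(learning_rate = 5e-4, weight_decay = 1e-8,
                          batch_size = 8L, max_epochs = 256L, patience = 50L,
                          validation_fraction = 0, verbose = FALSE) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 verbose = isTRUE(verbose)),
            class = "mvtsk_control")
}

#' Fit a multi-view TSK fuzzy classifier
#'
#' Fits a Takagi--Sugeno--Kang fuzzy classifier over several feature views of
#' the same samples. Each view gets its own antecedent network of deformable
#' Gaussian membership functions (trainable centers, center offsets and
#' widths; all firing computed in log space) and, in the full model, a
#' rule-level multi-head self-attention block that re-weights rule
#' activations per sample. Per-view simplex activations are fused by
#' learnable softmax-normalized view weights and fed to first-order linear
#' consequents over the concatenated features; class scores are trained with
#' cross-entropy via AdamW (decoupled weight decay) and early stopping.
#'
#' @param views a list of numeric matrices \code{[N x D_v]}, one per view and
#'   row-aligned, or a \code{multiview_dataset}.
#' @param labels class labels (factor or integer vector of length \code{N});
#'   ignored when \code{views} is a \code{multiview_dataset}.
#' @param n_rules number of fuzzy rules \code{R} shared by all views
#'   (default 51).
#' @param variant which components are active: \code{"full"} (deformable
#'   antecedents + attention), \code{"no_attention"} (deformable antecedents,
#'   uniform all-ones attention path), \code{"no_deform"} (attention with
#'   offsets frozen at zero), \code{"basic"} (neither).
#' @param n_heads requested attention heads (reduced to divide \code{D_v}).
#' @param fusion_domain \code{"log"} modulates log-firing with attention
#'   (default); \code{"linear"} modulates the exponentiated firing.
#' @param init center initialization strategy, \code{"sample"} or
#'   \code{"kmeans"} (see [init_rule_bank()]).
#' @param scale per-view feature scaling fitted on the supplied (training)
#'   data and reapplied by \code{predict}: \code{"minmax"}, \code{"standard"}
#'   or \code{"none"}. Exact zeros are shifted by 1e-8 before scaling.
#' @param seed integer seed governing initialization and batch shuffling.
#' @param control a [mvtsk_control()].
#' @return An object of class \code{"mvtsk"}: a list with trained
#'   \code{params} (per-view \code{centers}, \code{offsets}, \code{sigmas},
#'   attention blocks, \code{view_logits}, consequent \code{A}, \code{b}),
#'   \code{history} (per-epoch monitored loss), \code{best_epoch},
#'   \code{classes}, fitted scalers, and the call configuration.
#' @seealso [predict.mvtsk()], [extract_rule()], [run_protocol()]
#' @examples
#' d <- worked_example()
#' fit <- mvtsk(d$views, d$labels, n_rules = 4,
#'              control = mvtsk_control(max_epochs = 30), seed = 1)
#' predict(fit, d$views)
#' @export
mvtsk <- function(views, labels = NULL, n_rules = 51L,
                  variant = c("full", "no_attention", "no_deform", "basic"),
                  n_heads = 4L, fusion_domain = c("log", "linear"),
                  init = c("sample", "kmeans"),
                  scale = c("minmax", "standard", "none"),
                  seed = 1L, control = mvtsk_control()) {
  variant <- match.arg(variant)
  fusion_domain <- match.arg(fusion_domain)
  init <- match.arg(init)
  scale <- match.arg(scale)
  stopifnot(inherits(control, "mvtsk_control"))

  if (inherits(views, "multiview_dataset")) {
    labels <- views$labels
    views <- views$views
  }
  stopifnot(is.list(views), length(views) >= 1L)
  views <- lapply(views, as.matrix)
  N <- unique(vapply(views, nrow, integer(1)))
  if (length(N) != 1L) stop("all views must have the same number of rows", call. = FALSE)
  if (is.null(labels) || length(labels) != N)
    stop("labels must be supplied with length equal to the number of rows", call. = FALSE)

  fac <- as.factor(labels)
  y <- as.integer(fac) - 1L           # 0..C-1
  classes <- levels(fac)
  C <- length(classes)
  V <- length(views)
  R <- as.integer(n_rules)

  # preprocessing: zero shift then per-view scaling, fitted on these rows only
  scalers <- vector("list", V)
  Xs <- vector("list", V)
  for (v in seq_len(V)) {
    Xv <- shift_zeros(views[[v]])
    if (scale != "none") {
      scalers[[v]] <- fit_scaler(Xv, kind = scale)
      Xv <- apply_scaler(scalers[[v]], Xv)
    }
    Xs[[v]] <- Xv
  }

  struct <- list(V = V, R = R, C = C,
                 dims = vapply(Xs, ncol, integer(1)),
                 attention_on = variant %in% c("full", "no_deform"),
                 deform_on = variant %in% c("full", "no_attention"),
                 fusion_domain = fusion_domain)

  params <- init_mvtsk_params(Xs, struct, init, n_heads, seed)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  # optional validation split for the early-stopping monitor
  val_idx <- integer(0)
  train_idx <- seq_len(N)
  if (control$validation_fraction > 0) {
    sp <- split_stratified(y, fraction = 1 - control$validation_fraction,
                           seed = as.integer(seed) + 7919L)
    train_idx <- sp$train; val_idx <- sp$test
  }
  Xtr <- lapply(Xs, function(m) m[train_idx, , drop = FALSE])
  ytr <- y[train_idx]
  Xval <- if (length(val_idx)) lapply(Xs, function(m) m[val_idx, , drop = FALSE]) else NULL
  yval <- if (length(val_idx)) y[val_idx] else NULL

  fit <- train_loop(params, Xtr, ytr, Xval, yval, struct, control)

  out <- structure(
    list(params = fit$params, struct = struct, history = fit$history,
         best_epoch = fit$best_epoch, stopped_epoch = fit$stopped_epoch,
         classes = classes, variant = variant, n_rules = R,
         scalers = scalers, scale = scale,
         view_offsets = c(0L, cumsum(struct$dims))[seq_len(V)],
         seed = as.integer(seed), control = control,
         call = match.call()),
    class = "mvtsk")
  out
}

# ---- parameter initialization -------------------------------------------

init_mvtsk_params <- function(Xs, struct, init, n_heads, seed) {
  V <- struct$V; R <- struct$R; C <- struct$C
  Dtot <- sum(struct$dims)
  pv <- vector("list", V)
  names(pv) <- paste0("v", seq_len(V))
  for (v in seq_len(V)) {
    rb <- init_rule_bank(Xs[[v]], R, seed = as.integer(seed) + v,
                         strategy = init)
    att <- if (struct$attention_on)
      attention_params(struct$dims[v], R, n_heads = n_heads,
                       seed = as.integer(seed) + 100L + v)
    else NULL
    pv[[v]] <- list(centers = rb$centers, offsets = rb$offsets,
                    sigmas = rb$sigmas, attention = att)
  }
  list(views = pv,
       view_logits = numeric(V),
       A = array(0, dim = c(R, Dtot, C)),
       b = matrix(0, R, C))
}

# ---- forward pass --------------------------------------------------------

# Full-batch forward. Returns class scores, probabilities and (optionally)
# the per-view intermediates needed for backprop or diagnostics.
mvtsk_forward <- function(params, Xs, struct, keep_cache = FALSE) {
  V <- struct$V; R <- struct$R; C <- struct$C
  B <- nrow(Xs[[1L]])
  beta <- softmax_vec(params$view_logits)
  Fsum <- matrix(0, B, R)
  cache <- if (keep_cache) vector("list", V) else NULL
  alphas <- vector("list", V)
  fv_list <- vector("list", V)
  for (v in seq_len(V)) {
    p <- params$views[[v]]
    X <- Xs[[v]]
    M <- p$centers + p$offsets
    Z <- log_firing_batch(X, M, p$sigmas)
    if (struct$attention_on) {
      att <- p$attention
      heads <- vector("list", att$n_heads)
      dk <- att$D %/% att$n_heads
      for (i in seq_len(att$n_heads)) {
        Q <- X %*% att$Wq[[i]]; K <- X %*% att$Wk[[i]]; Vh <- X %*% att$Wv[[i]]
        w <- exp((rowSums(Q * K) / sqrt(dk)) * 0)   # softmax over one key: 1
        heads[[i]] <- w * Vh
      }
      Hcat <- do.call(cbind, heads)
      h <- Hcat %*% att$Wo
      s_att <- h %*% att$Wfc + rep_row(att$bfc, B)
      alpha <- softmax_rows(s_att)
    } else {
      alpha <- matrix(1, B, R)                       # all-ones attention path
      Hcat <- h <- NULL
    }
    if (struct$fusion_domain == "log") {
      u <- alpha * Z
    } else {
      u <- alpha * exp(Z)
    }
    fv <- softmax_rows(u)
    Fsum <- Fsum + beta[v] * fv
    alphas[[v]] <- alpha
    fv_list[[v]] <- fv
    if (keep_cache) cache[[v]] <- list(Z = Z, Hcat = Hcat, h = h, alpha = alpha)
  }
  Xc <- do.call(cbind, Xs)
  Y <- matrix(0, B, C)
  G <- vector("list", C)
  for (cc in seq_len(C)) {
    Gc <- tcrossprod(Xc, params$A[, , cc, drop = FALSE][, , 1L]) + rep_row(params$b[, cc], B)
    Y[, cc] <- rowSums(Fsum * Gc)
    if (keep_cache) G[[cc]] <- Gc
  }
  P <- softmax_rows(Y)
  list(scores = Y, probs = P, fused = Fsum, beta = beta,
       alphas = alphas, fv = fv_list, cache = cache, Xc = Xc, G = G)
}

# Mean cross-entropy of a forward pass against integer labels 0..C-1.
xent_loss <- function(P, y) {
  -mean(log(pmax(P[cbind(seq_along(y), y + 1L)], 1e-300)))
}

# ---- backward pass -------------------------------------------------------

# Analytic gradients of the mean cross-entropy w.r.t. every trainable array.
# Returns a nested list mirroring `params`. Attention Wq/Wk receive exactly
# zero gradient (single-token attention weights are constant 1).
mvtsk_backward <- function(params, Xs, y, struct, fw) {
  V <- struct$V; R <- struct$R; C <- struct$C
  B <- length(y)
  P <- fw$probs
  dY <- P
  dY[cbind(seq_len(B), y + 1L)] <- dY[cbind(seq_len(B), y + 1L)] - 1
  dY <- dY / B

  Xc <- fw$Xc
  Fsum <- fw$fused
  gA <- array(0, dim = dim(params$A))
  gb <- matrix(0, R, C)
  dF <- matrix(0, B, R)
  for (cc in seq_len(C)) {
    Gc <- fw$G[[cc]]
    dGc <- Fsum * dY[, cc]
    gA[, , cc] <- crossprod(dGc, Xc)          # [R x Dtot]
    gb[, cc] <- colSums(dGc)
    dF <- dF + dY[, cc] * Gc
  }

  beta <- fw$beta
  dbeta <- numeric(V)
  gviews <- vector("list", V)
  names(gviews) <- names(params$views)
  for (v in seq_len(V)) {
    p <- params$views[[v]]
    X <- Xs[[v]]
    cc_ <- fw$cache[[v]]
    fv <- fw$fv[[v]]
    alpha <- cc_$alpha
    Z <- cc_$Z
    dbeta[v] <- sum(dF * fv)
    dfv <- beta[v] * dF
    du <- fv * (dfv - rowSums(dfv * fv))      # softmax backward over rules
    if (struct$fusion_domain == "log") {
      dalpha <- du * Z
      dZ <- du * alpha
    } else {
      a_lin <- exp(Z)
      dalpha <- du * a_lin
      dZ <- du * alpha * a_lin
    }
    gatt <- NULL
    if (struct$attention_on) {
      att <- p$attention
      ds <- alpha * (dalpha - rowSums(dalpha * alpha))  # softmax backward
      gWfc <- crossprod(cc_$h, ds)
      gbfc <- colSums(ds)
      dh <- tcrossprod(ds, att$Wfc)           # [B x D]
      gWo <- crossprod(cc_$Hcat, dh)
      dHcat <- tcrossprod(dh, att$Wo)         # [B x D]
      dk <- att$D %/% att$n_heads
      hn <- paste0("h", seq_len(att$n_heads))
      gWv <- stats::setNames(vector("list", att$n_heads), hn)
      gWq <- stats::setNames(vector("list", att$n_heads), hn)
      gWk <- stats::setNames(vector("list", att$n_heads), hn)
      for (i in seq_len(att$n_heads)) {
        cols <- ((i - 1L) * dk + 1L):(i * dk)
        gWv[[i]] <- crossprod(X, dHcat[, cols, drop = FALSE])
        gWq[[i]] <- matrix(0, att$D, dk)
        gWk[[i]] <- matrix(0, att$D, dk)
      }
      gatt <- list(Wq = gWq, Wk = gWk, Wv = gWv, Wo = gWo, Wfc = gWfc, bfc = gbfc)
    }
    # antecedent gradients
    M <- p$centers + p$offsets
    S <- p$sigmas
    csdZ <- colSums(dZ)                       # [R]
    XtdZ <- crossprod(X, dZ)                  # [D x R]
    dM <- (XtdZ - M * rep(csdZ, each = nrow(M))) / S^2
    Qd <- crossprod(X^2, dZ) - 2 * M * XtdZ + M^2 * rep(csdZ, each = nrow(M))
    gsig <- Qd / S^3
    gviews[[v]] <- list(centers = dM,
                        offsets = if (struct$deform_on) dM else NULL,
                        sigmas = gsig,
                        attention = gatt)
  }
  dlogits <- beta * (dbeta - sum(dbeta * beta))
  list(views = gviews, view_logits = dlogits, A = gA, b = gb)
}

# ---- AdamW over the nested parameter structure ---------------------------

# Enumerate trainable leaves as [[-paths into the nested list.
param_paths <- function(params, struct) {
  paths <- list()
  for (v in seq_len(struct$V)) {
    nm <- names(params$views)[v]
    paths <- c(paths, list(c("views", nm, "centers")))
    if (struct$deform_on) paths <- c(paths, list(c("views", nm, "offsets")))
    paths <- c(paths, list(c("views", nm, "sigmas")))
    if (struct$attention_on) {
      att <- params$views[[v]]$attention
      for (i in seq_len(att$n_heads)) {
        hn <- paste0("h", i)
        paths <- c(paths,
                   list(c("views", nm, "attention", "Wq", hn),
                        c("views", nm, "attention", "Wk", hn),
                        c("views", nm, "attention", "Wv", hn)))
      }
      paths <- c(paths, list(c("views", nm, "attention", "Wo"),
                             c("views", nm, "attention", "Wfc"),
                             c("views", nm, "attention", "bfc")))
    }
  }
  c(paths, list("view_logits", "A", "b"))
}

adamw_init <- function(params, paths) {
  st <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    p <- params[[paths[[k]]]]
    st[[k]] <- list(m = p * 0, v = p * 0)
  }
  list(t = 0L, slots = st)
}

# One decoupled-weight-decay Adam step; sigmas clamped to stay positive.
adamw_step <- function(params, grads, state, paths, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(paths)) {
    path <- paths[[k]]
    g <- grads[[path]]
    if (is.null(g)) next
    p <- params[[path]]
    sl <- state$slots[[k]]
    sl$m <- beta1 * sl$m + (1 - beta1) * g
    sl$v <- beta2 * sl$v + (1 - beta2) * g^2
    p <- p - lr * (sl$m / bc1) / (sqrt(sl$v / bc2) + eps) - lr * wd * p
    if (identical(path[length(path)], "sigmas")) p <- pmax(p, 1e-4)
    params[[path]] <- p
    state$slots[[k]] <- sl
  }
  list(params = params, state = state)
}

# ---- training loop -------------------------------------------------------

train_loop <- function(params, Xtr, ytr, Xval, yval, struct, control) {
  N <- length(ytr)
  paths <- param_paths(params, struct)
  state <- adamw_init(params, paths)
  history <- numeric(0)
  best_loss <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  n_batches <- max(1L, ceiling(N / control$batch_size))
  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample.int(N)
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * control$batch_size + 1L):min(bi * control$batch_size, N)]
      Xb <- lapply(Xtr, function(m) m[idx, , drop = FALSE])
      yb <- ytr[idx]
      fw <- mvtsk_forward(params, Xb, struct, keep_cache = TRUE)
      loss <- xent_loss(fw$probs, yb)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d; last finite monitored loss %.6g",
                     epoch, if (length(history)) history[length(history)] else NA_real_),
             call. = FALSE)
      gr <- mvtsk_backward(params, Xb, yb, struct, fw)
      upd <- adamw_step(params, gr, state, paths,
                        lr = control$learning_rate, wd = control$weight_decay)
      params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + loss * length(idx)
    }
    epoch_loss <- epoch_loss / N
    monitored <- if (!is.null(Xval)) {
      fwv <- mvtsk_forward(params, Xval, struct, keep_cache = FALSE)
      xent_loss(fwv$probs, yval)
    } else epoch_loss
    history <- c(history, monitored)
    if (control$verbose)
      message(sprintf("epoch %3d  loss %.6f", epoch, monitored))
    if (monitored < best_loss - 1e-9) {
      best_loss <- monitored
      best_params <- params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) {
        if (control$verbose)
          message(sprintf("early stop at epoch %d (best epoch %d, loss %.6f)",
                          epoch, best_epoch, best_loss))
        break
      }
    }
  }
  list(params = best_params, history = history,
       best_epoch = best_epoch, stopped_epoch = length(history))
}
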