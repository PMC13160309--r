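test_that("stratified splitting preserves class proportions deterministically", {
  labels <- rep(c("A", "B"), each = 50)
  sp <- split_stratified(labels, fraction = 0.8, seed = 1)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  expect_identical(as.integer(table(labels[sp$train])), c(40L, 40L))
  expect_identical(as.integer(table(labels[sp$test])), c(10L, 10L))
  # determinism
  expect_identical(split_stratified(labels, 0.8, seed = 1), sp)
  # rounding on a small class inside a two-class set: 10 samples -> 8/2
  lab2 <- c(rep(0, 40), rep(1, 10))
  sp2 <- split_stratified(lab2, 0.8, seed = 3)
  expect_identical(sum(lab2[sp2$train] == 1), 8L)
  expect_identical(sum(lab2[sp2$test] == 1), 2L)
  # singleton class refuses to stratify
  expect_error(split_stratified(c(1, 1, 2), 0.8, seed = 1), "fewer than 2")
})

test_that("analytic gradients match finite differences on every parameter family", {
  set.seed(42)
  g <- generate_multiview(n_samples = 12, n_views = 2, dims = c(2, 3),
                          n_classes = 2, separation = 2, seed = 3)
  Xs <- g$dataset$views
  y <- g$dataset$labels
  struct <- list(V = 2L, R = 3L, C = 2L, dims = c(2L, 3L),
                 attention_on = TRUE, deform_on = TRUE, fusion_domain = "log")
  params <- fuzzyview:::init_mvtsk_params(Xs, struct, "sample", 2L, 7L)
  params$A[] <- rnorm(length(params$A), sd = 0.3)
  params$b[] <- rnorm(length(params$b), sd = 0.3)
  for (v in 1:2) {
    params$views[[v]]$attention$Wfc[] <- rnorm(length(params$views[[v]]$attention$Wfc), sd = 0.3)
    params$views[[v]]$offsets[] <- rnorm(length(params$views[[v]]$offsets), sd = 0.2)
  }
  params$view_logits <- c(0.3, -0.2)
  fw <- fuzzyview:::mvtsk_forward(params, Xs, struct, keep_cache = TRUE)
  gr <- fuzzyview:::mvtsk_backward(params, Xs, y, struct, fw)
  lossfun <- function(p) {
    f <- fuzzyview:::mvtsk_forward(p, Xs, struct, FALSE)
    fuzzyview:::xent_loss(f$probs, y)
  }
  for (pt in fuzzyview:::param_paths(params, struct)) {
    g0 <- gr[[pt]]
    ii <- sample(length(params[[pt]]), min(3, length(params[[pt]])))
    for (i in ii) {
      eps <- 1e-6
      pp <- params; pp[[pt]][i] <- pp[[pt]][i] + eps
      pm <- params; pm[[pt]][i] <- pm[[pt]][i] - eps
      fd <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      denom <- max(1e-6, abs(fd), abs(g0[i]))
      expect_lt(abs(fd - g0[i]) / denom, 1e-4,
                label = sprintf("gradient of %s[%d]", paste(pt, collapse = "."), i))
    }
  }
})

test_that("one AdamW step on a single sample decreases its loss", {
  g <- tiny_problem()
  struct <- list(V = 2L, R = 2L, C = 2L, dims = c(3L, 2L),
                 attention_on = TRUE, deform_on = TRUE, fusion_domain = "log")
  params <- fuzzyview:::init_mvtsk_params(
    lapply(g$dataset$views, function(m) m[1:6, , drop = FALSE]), struct, "sample", 2L, 5L)
  Xs <- lapply(g$dataset$views, function(m) m[1, , drop = FALSE])
  y <- g$dataset$labels[1]
  params$A[] <- rnorm(length(params$A), sd = 0.2)
  paths <- fuzzyview:::param_paths(params, struct)
  st <- fuzzyview:::adamw_init(params, paths)
  fw <- fuzzyview:::mvtsk_forward(params, Xs, struct, TRUE)
  l0 <- fuzzyview:::xent_loss(fw$probs, y)
  gr <- fuzzyview:::mvtsk_backward(params, Xs, y, struct, fw)
  upd <- fuzzyview:::adamw_step(params, gr, st, paths, lr = 1e-4, wd = 0)
  fw1 <- fuzzyview:::mvtsk_forward(upd$params, Xs, struct, FALSE)
  expect_lt(fuzzyview:::xent_loss(fw1$probs, y), l0)
})

test_that("training is reproducible and fits a degenerate single-class set", {
  g <- tiny_problem()
  f1 <- mvtsk(g$dataset$views, g$dataset$labels, n_rules = 3,
              control = fast_control(10), seed = 4)
  f2 <- mvtsk(g$dataset$views, g$dataset$labels, n_rules = 3,
              control = fast_control(10), seed = 4)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$params, f2$params)
  # single-class data: training accuracy 1 after a few epochs
  ones <- rep(1L, 20)
  f3 <- mvtsk(lapply(g$dataset$views, function(m) m[1:20, , drop = FALSE]),
              ones, n_rules = 2, control = fast_control(3), seed = 1)
  pr <- predict(f3, lapply(g$dataset$views, function(m) m[1:20, , drop = FALSE]))
  expect_true(all(as.character(pr) == "1"))
})

test_that("variants freeze or drop exactly the advertised components", {
  g <- tiny_problem()
  fits <- lapply(c("full", "no_attention", "no_deform", "basic"), function(vr)
    mvtsk(g$dataset$views, g$dataset$labels, n_rules = 3, variant = vr,
          control = fast_control(8), seed = 5))
  names(fits) <- c("full", "no_attention", "no_deform", "basic")
  # frozen offsets stay exactly zero after training
  for (vr in c("no_deform", "basic"))
    for (pv in fits[[vr]]$params$views)
      expect_true(all(pv$offsets == 0))
  # deformable variants actually move their offsets
  for (vr in c("full", "no_attention"))
    expect_gt(max(abs(unlist(lapply(fits[[vr]]$params$views, `[[`, "offsets")))), 0)
  # attention blocks exist exactly where advertised
  for (vr in c("full", "no_deform"))
    expect_s3_class(fits[[vr]]$params$views[[1]]$attention, "attention_params")
  for (vr in c("no_attention", "basic"))
    expect_null(fits[[vr]]$params$views[[1]]$attention)
  # full and no_attention differ only by the attention parameter count
  n_trainable <- function(fit) {
    paths <- fuzzyview:::param_paths(fit$params, fit$struct)
    sum(vapply(paths, function(pt) length(fit$params[[pt]]), numeric(1)))
  }
  att_len <- sum(unlist(lapply(fits$full$params$views, function(p)
    sum(vapply(p$attention[c("Wq", "Wk", "Wv")],
               function(l) sum(vapply(l, length, numeric(1))), numeric(1))) +
      length(p$attention$Wo) + length(p$attention$Wfc) + length(p$attention$bfc))))
  expect_equal(n_trainable(fits$full) - n_trainable(fits$no_attention), att_len)
})

test_that("the no-attention variant forward equals a direct multi-view TSK oracle", {
  # standard memberships + classic normalized firing per view + convex view
  # fusion + linear consequents, assembled independently of the package path
  set.seed(99)
  for (trial in 1:10) {
    V <- 2; R <- 3; C <- 2; dims <- c(2, 3)
    pv <- list()
    for (v in 1:V) {
      D <- dims[v]
      pv[[paste0("v", v)]] <- list(
        centers = matrix(rnorm(D * R), D, R),
        offsets = matrix(0, D, R),
        sigmas = matrix(runif(D * R, 0.5, 2), D, R),
        attention = NULL)
    }
    logits <- rnorm(V)
    Dtot <- sum(dims)
    A <- array(rnorm(R * Dtot * C, sd = 0.4), c(R, Dtot, C))
    b <- matrix(rnorm(R * C), R, C)
    struct <- list(V = 2L, R = 3L, C = 2L, dims = as.integer(dims),
                   attention_on = FALSE, deform_on = TRUE, fusion_domain = "log")
    m <- manual_model(pv, logits, A, b, struct)
    xs <- list(rnorm(2), rnorm(3))
    got <- drop(predict(m, lapply(xs, function(x) matrix(x, 1)), type = "score"))
    # oracle
    beta <- exp(logits) / sum(exp(logits))
    fused <- numeric(R)
    for (v in 1:V) {
      firing <- vapply(1:R, function(r)
        prod(exp(-(xs[[v]] - pv[[v]]$centers[, r])^2 / (2 * pv[[v]]$sigmas[, r]^2))),
        numeric(1))
      fused <- fused + beta[v] * firing / sum(firing)
    }
    xc <- c(xs[[1]], xs[[2]])
    want <- vapply(1:C, function(cc)
      sum(fused * vapply(1:R, function(r) sum(A[r, , cc] * xc) + b[r, cc],
                         numeric(1))), numeric(1))
    expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("early stopping waits out the patience window and restores the best epoch", {
  g <- tiny_problem(n = 40)
  ctl <- mvtsk_control(max_epochs = 60, patience = 5)
  fit <- mvtsk(g$dataset$views, g$dataset$labels, n_rules = 2,
               control = ctl, seed = 6)
  expect_lte(fit$stopped_epoch, 60)
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  if (fit$stopped_epoch < 60)   # stopped early: exactly patience epochs idle
    expect_identical(fit$stopped_epoch - fit$best_epoch, 5L)
  expect_equal(fit$history[fit$best_epoch], min(fit$history))
})

test_that("trained antecedents land near the true synthetic cluster structure", {
  # parameter-recovery proxy: on well-separated data, shifted centers end up
  # within 2 (post-scaling) units of a true class prototype for most rules
  g <- generate_multiview(n_samples = 150, n_views = 1, dims = 3,
                          n_classes = 3, separation = 8, noise_sd = 0.1,
                          seed = 13)
  fit <- mvtsk(g$dataset$views, g$dataset$labels, n_rules = 6,
               control = fast_control(60), seed = 13)
  # class prototypes in the scaled feature space the model actually saw
  Xs <- fuzzyview:::prepare_views(fit, g$dataset$views)[[1]]
  proto <- t(sapply(0:2, function(k) colMeans(Xs[g$dataset$labels == k, ])))
  ctr <- fit$params$views[[1]]$centers + fit$params$views[[1]]$offsets
  near <- vapply(seq_len(ncol(ctr)), function(r)
    min(sqrt(rowSums(sweep(proto, 2, ctr[, r])^2))), numeric(1))
  expect_gte(mean(near < 2), 0.5)
})
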