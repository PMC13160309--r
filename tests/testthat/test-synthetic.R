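test_that("generated data has the configured shapes, balance and determinism", {
  g <- generate_multiview(n_samples = 31, n_views = 3, dims = c(4, 2, 5),
                          n_classes = 4, seed = 9)
  expect_length(g$dataset$views, 3)
  expect_identical(unname(vapply(g$dataset$views, dim, integer(2))[1, ]), rep(31L, 3))
  expect_identical(unname(vapply(g$dataset$views, dim, integer(2))[2, ]), c(4L, 2L, 5L))
  expect_true(all(g$dataset$labels %in% 0:3))
  expect_lte(diff(range(table(g$dataset$labels))), 1)   # round-robin balance
  g2 <- generate_multiview(n_samples = 31, n_views = 3, dims = c(4, 2, 5),
                           n_classes = 4, seed = 9)
  expect_identical(g$dataset$views, g2$dataset$views)
  expect_identical(g$truth$latent, g2$truth$latent)
})

test_that("a latent nearest-center oracle separates well-separated classes", {
  g <- generate_multiview(n_samples = 400, n_views = 2, n_classes = 3,
                          separation = 6, noise_sd = 0.1, seed = 1)
  Z <- g$truth$latent
  ctr <- g$truth$latent_centers
  pred <- apply(Z, 1, function(z)
    which.min(colSums((t(ctr) - z)^2)) - 1L)
  expect_gte(mean(pred == g$dataset$labels), 0.99)
  # pairwise center distances equal the requested separation
  dd <- dist(ctr)
  expect_equal(as.numeric(dd), rep(6, length(dd)), tolerance = 1e-12)
})

test_that("separation = 0 carries no class signal", {
  g <- generate_multiview(n_samples = 200, n_views = 2, n_classes = 2,
                          separation = 0, seed = 6)
  # the latent distribution is label-independent: a nearest-center oracle
  # has coincident centers, and view features decorrelate from labels
  expect_equal(g$truth$latent_centers[1, ], g$truth$latent_centers[2, ])
  cors <- abs(cor(g$dataset$views[[1]], g$dataset$labels))
  expect_lt(max(cors), 0.25)
})

test_that("redundant views are corrupted copies of their source", {
  g <- generate_multiview(n_samples = 50, n_views = 2, dims = c(3, 2),
                          n_classes = 2, separation = 4, noise_sd = 0.1,
                          redundant_views = list(list(source = 1, corruption_sd = 0.5)),
                          seed = 2)
  expect_length(g$dataset$views, 3)
  diffs <- g$dataset$views[[3]] - g$dataset$views[[1]]
  expect_equal(dim(diffs), c(50L, 3L))
  expect_lt(abs(sd(as.numeric(diffs)) - 0.5), 0.1)
  expect_gt(cor(as.numeric(g$dataset$views[[3]]), as.numeric(g$dataset$views[[1]])), 0.8)
})

test_that("the worked example is fixed, balanced and starts from uniform class scores", {
  d <- worked_example()
  expect_identical(vapply(d$views, nrow, integer(1)), c(12L, 12L))
  expect_identical(vapply(d$views, ncol, integer(1)), c(2L, 3L))
  expect_identical(as.integer(table(d$labels)), c(6L, 6L))
  expect_identical(worked_example(), d)   # hard-coded
  # zero-initialized consequents: uniform class scores before training
  struct <- list(V = 2L, R = 3L, C = 2L, dims = c(2L, 3L),
                 attention_on = TRUE, deform_on = TRUE, fusion_domain = "log")
  params <- fuzzyview:::init_mvtsk_params(d$views, struct, "sample", 2L, 1L)
  fw <- fuzzyview:::mvtsk_forward(params, d$views, struct, FALSE)
  expect_equal(fw$probs, matrix(0.5, 12, 2), tolerance = 1e-12)
})

test_that("test accuracy is non-decreasing in class separation", {
  seps <- c(0, 2, 6)
  mean_acc <- vapply(seps, function(s) {
    accs <- vapply(1:3, function(k) {
      g <- generate_multiview(n_samples = 120, n_views = 2, dims = c(4, 3),
                              n_classes = 2, separation = s, noise_sd = 0.2,
                              seed = 20 + k)
      sp <- split_stratified(g$dataset$labels, 0.8, seed = k)
      fit <- mvtsk(lapply(g$dataset$views, function(m) m[sp$train, , drop = FALSE]),
                   g$dataset$labels[sp$train], n_rules = 4,
                   control = fast_control(30), seed = k)
      pr <- predict(fit, lapply(g$dataset$views, function(m) m[sp$test, , drop = FALSE]))
      mean(as.character(pr) == as.character(g$dataset$labels[sp$test]))
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(mean_acc) >= -0.05))
  expect_gt(mean_acc[3], mean_acc[1])
})
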