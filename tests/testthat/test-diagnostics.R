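test_that("attention_entropy computes Shannon entropy in nats", {
  expect_equal(attention_entropy(rep(1 / 51, 51)), log(51))
  expect_equal(attention_entropy(c(1, 0, 0, 0)), 0)           # 0 ln 0 := 0
  expect_equal(attention_entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_error(attention_entropy(c(0.9, -0.1, 0.2)), "non-negative")
  expect_error(attention_entropy(c(0.5, 0.4)), "simplex")
  # renormalization inside the 1e-6 tolerance band
  w <- rep(1 / 4, 4) * (1 + 2e-7)
  expect_equal(attention_entropy(w), log(4), tolerance = 1e-9)
})

test_that("rule_usage derives effective rules, proportions and top-k from the weights", {
  # uniform over 51 rules with k = 5
  u <- rule_usage(rep(1 / 51, 51), k = 5)
  expect_equal(u$effective_rules, 51)
  expect_equal(u$normalized_entropy, 1)
  expect_equal(u$proportion_active, 1)
  expect_equal(u$top_k_contribution, 5 / 51)
  expect_error(rule_usage(rep(1 / 4, 4), k = 9), "1..R")
  # perplexity identities hold on arbitrary simplex vectors
  set.seed(14)
  for (trial in 1:20) {
    w <- rexp(12); w <- w / sum(w)
    u <- rule_usage(w, k = 3)
    expect_equal(u$effective_rules, exp(u$entropy))
    expect_equal(u$proportion_active, u$effective_rules / 12)
    expect_equal(u$normalized_entropy, u$entropy / log(12))
    expect_lte(u$normalized_entropy, 1 + 1e-12)
    # top-k contribution is monotone in k and reaches 1 at k = R
    tk <- vapply(1:12, function(k) rule_usage(w, k)$top_k_contribution,
                 numeric(1))
    expect_true(all(diff(tk) >= -1e-12))
    expect_equal(tk[12], 1)
  }
})

test_that("entropy-derived statistics reproduce the shipped reference table", {
  ref <- read.csv(system.file("extdata", "rule_attention_entropy_reference.csv",
                              package = "fuzzyview"))
  expect_identical(nrow(ref), 15L)
  for (i in seq_len(nrow(ref))) {
    st <- rule_usage_from_entropy(ref$entropy[i], R = 51)
    # printed values are rounded; agreement to the printed last digit
    expect_lt(abs(st$effective_rules - ref$effective_rules[i]), 0.01)
    expect_lt(abs(st$normalized_entropy - ref$normalized_entropy[i]), 1e-4)
    expect_lt(abs(100 * st$proportion_active - ref$proportion_pct[i]), 0.011)
  }
})

test_that("param_stats uses the population (1/N) convention", {
  ps <- param_stats(c(1, 1, 1), "center")
  expect_equal(ps$mean, 1); expect_equal(ps$sd, 0)
  ps2 <- param_stats(c(0, 2), "sigma")
  expect_equal(ps2$mean, 1); expect_equal(ps2$sd, 1)   # not the n-1 value
  # translation shifts the mean, leaves the spread alone
  set.seed(3)
  v <- rnorm(40)
  expect_equal(param_stats(v + 5, "offset")$sd, param_stats(v, "offset")$sd)
  expect_equal(param_stats(v + 5, "offset")$mean,
               param_stats(v, "offset")$mean + 5)
  expect_equal(unname(param_stats(v, "center")$quartiles[3]),
               unname(quantile(v, 0.5)))
  expect_error(param_stats(numeric(0), "center"), "empty")
})

test_that("mean attention over samples stays on the simplex and averages linearly", {
  g <- tiny_problem()
  fit <- mvtsk(g$dataset$views, g$dataset$labels, n_rules = 4,
               control = fast_control(10), seed = 3)
  w <- mean_attention_over_samples(fit, g$dataset$views, view = 1)
  expect_length(w, 4)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w > 0))
  # one sample: that sample's weights exactly
  one <- lapply(g$dataset$views, function(m) m[3, , drop = FALSE])
  w1 <- mean_attention_over_samples(fit, one, view = 2)
  Xs <- fuzzyview:::prepare_views(fit, one)
  fw <- fuzzyview:::mvtsk_forward(fit$params, Xs, fit$struct, FALSE)
  expect_equal(w1, drop(fw$alphas[[2]]))
  # linearity: mean over two samples is the average of the per-sample weights
  two <- lapply(g$dataset$views, function(m) m[4:5, , drop = FALSE])
  wa <- mean_attention_over_samples(fit, lapply(g$dataset$views, function(m) m[4, , drop = FALSE]), 1)
  wb <- mean_attention_over_samples(fit, lapply(g$dataset$views, function(m) m[5, , drop = FALSE]), 1)
  expect_equal(mean_attention_over_samples(fit, two, 1), (wa + wb) / 2,
               tolerance = 1e-12)
  # attention-free variants report exactly uniform usage
  fb <- mvtsk(g$dataset$views, g$dataset$labels, n_rules = 4,
              variant = "basic", control = fast_control(3), seed = 3)
  expect_equal(mean_attention_over_samples(fb, g$dataset$views, 1), rep(0.25, 4))
  expect_error(mean_attention_over_samples(fit, g$dataset$views, 9), "out of range")
})
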