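# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except the shipped reference CSV.

# A small separable two-view, two-class problem for fast training tests.
tiny_problem <- function(n = 60, seed = 11) {
  generate_multiview(n_samples = n, n_views = 2, dims = c(3, 2),
                     n_classes = 2, separation = 5, noise_sd = 0.1,
                     seed = seed)
}

fast_control <- function(epochs = 40) {
  mvtsk_control(max_epochs = epochs, patience = epochs, batch_size = 8)
}

# Independent oracle: a standard first-order TSK system over one view,
# computed directly from the defining product/normalization form (no log
# space, no attention). centers/sigmas [D x R]; A [R x D x C]; b [R x C].
oracle_tsk <- function(x, centers, sigmas, A, b) {
  D <- nrow(centers); R <- ncol(centers); C <- ncol(b)
  firing <- vapply(seq_len(R), function(r) {
    prod(exp(-(x - centers[, r])^2 / (2 * sigmas[, r]^2)))
  }, numeric(1))
  w <- firing / sum(firing)
  scores <- numeric(C)
  for (cc in seq_len(C)) {
    yr <- vapply(seq_len(R), function(r) sum(A[r, , cc] * x) + b[r, cc], numeric(1))
    scores[cc] <- sum(w * yr)
  }
  scores
}

# Build an mvtsk-shaped model object around given parameters, bypassing
# training, so structural reductions can be tested against oracles.
manual_model <- function(views_params, view_logits, A, b, struct,
                         classes = as.character(seq_len(struct$C) - 1L)) {
  structure(
    list(params = list(views = views_params, view_logits = view_logits,
                       A = A, b = b),
         struct = struct, history = numeric(0), best_epoch = 0L,
         stopped_epoch = 0L, classes = classes, variant = "manual",
         n_rules = struct$R, scalers = vector("list", struct$V),
         scale = "none",
         view_offsets = c(0L, cumsum(struct$dims))[seq_len(struct$V)],
         seed = 0L, control = NULL, call = NULL),
    class = "mvtsk")
}
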