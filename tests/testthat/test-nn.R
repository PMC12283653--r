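# The network engine is hand-written; its backward pass is verified against
# central finite differences on small random instances of each architecture.

numeric_grad_gap <- function(kind, n = 4L, Tn = 5L, F = 3L, seed = 99L) {
  set.seed(seed)
  x <- array(rnorm(n * Tn * F), c(n, Tn, F))
  y <- matrix(rnorm(n * Tn), n, Tn)
  Xl <- crownprof:::x_to_list(x)
  p <- crownprof:::nn_init(kind, F, filters = 4L, units = 4L, seed = seed)
  fw <- crownprof:::nn_forward(p, Xl, kind)
  dY <- 2 * (fw$yhat - y) / length(y)
  g <- crownprof:::nn_backward(p, fw$cache, dY, kind)
  g$dX <- NULL
  flat_p <- unlist(p)
  flat_g <- unlist(g[names(p)])
  eps <- 1e-5
  num <- vapply(seq_along(flat_p), function(i) {
    pp <- flat_p; pp[i] <- pp[i] + eps
    pm <- flat_p; pm[i] <- pm[i] - eps
    (crownprof:::nn_loss(utils::relist(pp, p), Xl, y, kind) -
       crownprof:::nn_loss(utils::relist(pm, p), Xl, y, kind)) / (2 * eps)
  }, numeric(1))
  max(abs(num - flat_g)) / max(abs(flat_g))
}

test_that("analytic gradients match finite differences for every architecture", {
  for (kind in c("vanilla_lstm", "cnn_lstm", "cnn_lstm_attention")) {
    expect_lt(numeric_grad_gap(kind), 1e-6)
  }
})

test_that("models honour the [n, 10, F] -> [n, 10] shape contract", {
  set.seed(50)
  x <- array(runif(8 * 10 * 14), c(8, 10, 14))
  for (kind in c("vanilla_lstm", "cnn_lstm", "cnn_lstm_attention")) {
    p <- crownprof:::nn_init(kind, 14L, filters = 8L, units = 8L, seed = 1L)
    out <- crownprof:::nn_forward(p, crownprof:::x_to_list(x), kind)
    expect_equal(dim(out$yhat), c(8L, 10L))
    expect_true(all(is.finite(out$yhat)))
  }
})

test_that("attention weights form a distribution over the 10 steps", {
  set.seed(51)
  x <- array(rnorm(6 * 10 * 5), c(6, 10, 5))
  p <- crownprof:::nn_init("cnn_lstm_attention", 5L, filters = 4L,
                           units = 4L, seed = 2L)
  fw <- crownprof:::nn_forward(p, crownprof:::x_to_list(x),
                               "cnn_lstm_attention")
  A <- fw$cache$attn$A
  expect_equal(dim(A), c(6L, 10L))
  expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-12)
  expect_true(all(A >= 0))
})

test_that("parameter counts follow the architecture formulas", {
  count <- function(kind) {
    p <- crownprof:::nn_init(kind, 14L, filters = 16L, units = 32L, seed = 1L)
    length(unlist(p))
  }
  Fd <- 14L; f <- 16L; H <- 32L; ker <- 3L
  lstm_n <- function(d) d * 4 * H + H * 4 * H + 4 * H
  head_n <- H + 1L
  expect_equal(count("vanilla_lstm"), lstm_n(Fd) + head_n)
  conv_n <- ker * Fd * f + f + ker * f * 2 * f + 2 * f
  proj_n <- Fd * 2 * f + 2 * f
  expect_equal(count("cnn_lstm"), conv_n + proj_n + lstm_n(2L * f) + head_n)
  # attention adds exactly one scoring vector and bias
  expect_equal(count("cnn_lstm_attention") - count("cnn_lstm"), H + 1L)
})

test_that("a small model memorizes a tiny dataset", {
  set.seed(52)
  n <- 20L
  x <- array(runif(n * 10 * 5), c(n, 10, 5))
  y <- matrix(0, n, 10)
  for (t in 1:10) y[, t] <- 0.5 * x[, t, 1] + 0.3 * x[, t, 2]^2
  seqs <- structure(list(x = x, y = y, plot_id = rep("P", n),
                         tree_id = seq_len(n), direction = "mean",
                         feature_names = paste0("f", 1:5),
                         step_order = "top_down"),
                    class = "crown_sequences")
  cfg <- model_config("cnn_lstm", filters = 16L, lstm_units = 32L,
                      learning_rate = 5e-3, batch_size = 20L,
                      max_epochs = 500L, patience = 500L, seed = 3L,
                      allow_outside = TRUE)
  m <- build_model(cfg, 5L)
  m <- train_model(m, seqs, seqs)
  expect_lt(min(m$history$train_loss), 1e-3)
})

test_that("training is deterministic under the seed and restores the best epoch", {
  fi <- local({
    stand <- make_test_stand(n_trees = 15L, seed = 4L)
    pr <- crown_profiles(stand)
    seqs <- build_sequences(stand, pr, NULL, use_cpci = FALSE)
    parts <- split_dataset(seqs, seed = 1)
    nrm <- suppressWarnings(fit_normalizer(parts$train))
    list(tr = transform_sequences(nrm, parts$train),
         va = transform_sequences(nrm, parts$val), nrm = nrm)
  })
  cfg <- model_config("vanilla_lstm", lstm_units = 32L, learning_rate = 3e-3,
                      max_epochs = 30L, patience = 30L, seed = 9L)
  m1 <- train_model(build_model(cfg, 13L), fi$tr, fi$va, normalizer = fi$nrm)
  m2 <- train_model(build_model(cfg, 13L), fi$tr, fi$va, normalizer = fi$nrm)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  # restored weights reproduce the minimum validation loss
  Xva <- crownprof:::x_to_list(fi$va$x)
  restored <- crownprof:::nn_loss(m1$params, Xva, fi$va$y, "vanilla_lstm")
  expect_equal(restored, min(m1$history$val_loss), tolerance = 1e-12)
})

test_that("predictions are invariant under relabeling within a batch", {
  set.seed(53)
  x <- array(runif(6 * 10 * 5), c(6, 10, 5))
  p <- crownprof:::nn_init("cnn_lstm_attention", 5L, filters = 4L,
                           units = 4L, seed = 7L)
  out <- crownprof:::nn_forward(p, crownprof:::x_to_list(x),
                                "cnn_lstm_attention")$yhat
  perm <- c(4, 2, 6, 1, 3, 5)
  out_p <- crownprof:::nn_forward(p, crownprof:::x_to_list(
    x[perm, , , drop = FALSE]), "cnn_lstm_attention")$yhat
  expect_equal(out_p, out[perm, ], tolerance = 1e-12)
})
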