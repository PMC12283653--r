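test_that("metric suite reproduces hand-computed values and limits", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$mse, 1 / 3)
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-6)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$me, -1 / 3)
  expect_equal(m$r2, 0.5)
  # perfect fit
  p <- compute_metrics(c(0.4, 1.1, 2), c(0.4, 1.1, 2))
  expect_equal(unlist(p[c("mse", "rmse", "mae", "me")]), rep(0, 4),
               ignore_attr = TRUE)
  expect_equal(p$r2, 1)
  # predicting the mean gives R2 = 0
  y <- c(1, 2, 3, 4)
  n0 <- compute_metrics(y, rep(mean(y), 4))
  expect_equal(n0$r2, 0)
  # zero-variance observations: R2 undefined
  expect_warning(z <- compute_metrics(rep(2, 5), rnorm(5)), "zero variance")
  expect_true(is.nan(z$r2))
  expect_error(compute_metrics(1:3, 1:4), "equal length")
})

test_that("metrics agree with a brute-force recomputation on random data", {
  set.seed(60)
  y <- runif(200, 0, 3)
  yh <- y + rnorm(200, 0, 0.2)
  m <- compute_metrics(y, yh)
  expect_equal(m$mse, sum((y - yh)^2) / 200, tolerance = 1e-12)
  expect_equal(m$mae, sum(abs(y - yh)) / 200, tolerance = 1e-12)
  expect_equal(m$me, sum(y - yh) / 200, tolerance = 1e-12)
  expect_equal(m$r2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_true(m$mae >= abs(m$me))
  # invariances: R2 under common affine maps; MSE scales quadratically
  m2 <- compute_metrics(2 * y + 1, 2 * yh + 1)
  expect_equal(m2$r2, m$r2, tolerance = 1e-12)
  expect_equal(m2$mse, 4 * m$mse, tolerance = 1e-12)
})

test_that("evaluation matrix assembles the factorial report", {
  set.seed(61)
  mk <- function(arch, uc) list(arch = arch, direction = "mean",
                                use_cpci = uc, observed = runif(30),
                                predicted = runif(30))
  entries <- c(lapply(c("vanilla_lstm", "cnn_lstm", "cnn_lstm_attention"),
                      mk, uc = FALSE),
               lapply(c("vanilla_lstm", "cnn_lstm", "cnn_lstm_attention"),
                      mk, uc = TRUE))
  rep_ <- evaluation_matrix(entries)
  expect_equal(nrow(rep_), 6L)
  expect_equal(sum(rep_$use_cpci), 3L)
  # regenerable bit-identically from the same predictions
  expect_identical(rep_, evaluation_matrix(entries))
  # a missing cell is reported as absent, not an error
  entries[[2]]$predicted <- NULL
  rep2 <- evaluation_matrix(entries)
  expect_true(is.na(rep2$mse_m2[2]))
  # best cells are starred in the text rendering
  txt <- format_report(rep_)
  expect_length(txt, 7L)
  expect_true(any(grepl("\\*", txt)))
})

test_that("lagged radius dominates feature importance on synthetic stands", {
  gen <- generate_stand(stand_params(n_trees = 60L, gamma = 0.5), seed = 5L)
  stand <- apply_filters(gen$stand)$kept
  prof <- crown_profiles(stand)
  tab <- compute_cpci(stand, prof)
  seqs <- build_sequences(stand, prof, tab, use_cpci = TRUE)
  parts <- split_dataset(seqs, seed = 2L)
  nrm <- suppressWarnings(fit_normalizer(parts$train))
  cfg <- model_config("cnn_lstm", learning_rate = 3e-3, max_epochs = 120L,
                      seed = 2L)
  m <- train_model(build_model(cfg, 14L), transform_sequences(nrm, parts$train),
                   transform_sequences(nrm, parts$val), normalizer = nrm)
  imp <- permutation_importance(m, parts$test, n_repeats = 3L, seed = 1L)
  # the previous layer's radius is the dominant predictor, and the crown
  # width allometry ranks among the leading drivers
  expect_equal(imp$feature[1], "CR_lag")
  expect_lte(imp$rank[imp$feature == "CW"], 5L)
})

test_that("permutation importance is zero for disconnected features and reproducible", {
  set.seed(62)
  n <- 30L
  x <- array(runif(n * 10 * 4), c(n, 10, 4))
  y <- matrix(0, n, 10)
  for (t in 1:10) y[, t] <- x[, t, 1] + 0.5 * x[, t, 2]
  seqs <- structure(list(x = x, y = y, plot_id = rep("P", n),
                         tree_id = seq_len(n), direction = "mean",
                         feature_names = c("f1", "f2", "CH", "CR_lag"),
                         step_order = "top_down"),
                    class = "crown_sequences")
  cfg <- model_config("vanilla_lstm", lstm_units = 32L, learning_rate = 5e-3,
                      batch_size = 30L, max_epochs = 150L, patience = 150L,
                      seed = 5L)
  parts <- list(train = seqs, val = seqs)
  nrm <- fit_normalizer(seqs)
  trn <- transform_sequences(nrm, seqs)
  m <- train_model(build_model(cfg, 4L), trn, trn, normalizer = nrm)
  # sever feature 4 from the network: its input weights set to zero
  lag_idx <- 4L
  m$params$lstm$Wx[lag_idx, ] <- 0
  imp <- permutation_importance(m, seqs, n_repeats = 3L, seed = 1L)
  expect_equal(imp$importance[imp$feature == "CR_lag"], 0, tolerance = 1e-12)
  # the dominant driver ranks first
  expect_equal(imp$feature[1], "f1")
  imp2 <- permutation_importance(m, seqs, n_repeats = 3L, seed = 1L)
  expect_identical(imp, imp2)
  expect_error(permutation_importance(m, seqs, n_repeats = 0L), "n_repeats")
})
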