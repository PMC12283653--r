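make_feature_inputs <- function(n_trees = 15L, seed = 4L) {
  stand <- make_test_stand(n_trees = n_trees, seed = seed)
  pr <- crown_profiles(stand)
  tab <- compute_cpci(stand, pr)
  list(stand = stand, profiles = pr, cpci = tab)
}

test_that("sequences carry the documented feature layout", {
  fi <- make_feature_inputs()
  seqs <- build_sequences(fi$stand, fi$profiles, fi$cpci, use_cpci = TRUE)
  expect_equal(dim(seqs$x)[2:3], c(10L, 14L))
  expect_equal(seqs$feature_names, feature_names())
  seqs13 <- build_sequences(fi$stand, fi$profiles, NULL, use_cpci = FALSE)
  expect_equal(dim(seqs13$x)[3], 13L)
  expect_error(build_sequences(fi$stand, fi$profiles, NULL, use_cpci = TRUE),
               "requires a competition table")
  # CH_k = 0.1 k LCL
  dv <- derive_variables(fi$stand)
  i <- 3L
  expect_equal(seqs$x[i, , "CH"], 0.1 * (1:10) * dv$lcl[i], tolerance = 1e-12)
  # lag: 0 at the top step, then the previous step's target
  expect_equal(unname(seqs$x[i, 1, "CR_lag"]), 0)
  expect_equal(unname(seqs$x[i, 2:10, "CR_lag"]), seqs$y[i, 1:9],
               tolerance = 1e-12)
  # static features constant across steps
  for (f in c("AGE", "DBH", "TH", "CW", "HCW", "HCB", "LCL", "TSC", "CLR")) {
    expect_equal(length(unique(seqs$x[i, , f])), 1L)
  }
  # targets equal the interpolated MEAN profile layers
  one <- fi$profiles[fi$profiles$tree_id == fi$stand$trees$tree_id[i] &
                       fi$profiles$direction == "MEAN", ]
  expect_equal(seqs$y[i, ], one$cr[-1], tolerance = 1e-12)
})

test_that("missing HCW is imputed with the plot mean", {
  fi <- make_feature_inputs()
  fi$stand$trees$hcw_m[2] <- NA
  seqs <- build_sequences(fi$stand, fi$profiles, fi$cpci, use_cpci = TRUE)
  expect_equal(unname(seqs$x[2, 1, "HCW"]),
               mean(fi$stand$trees$hcw_m, na.rm = TRUE))
  expect_false(anyNA(seqs$x))
})

test_that("directional sequences use the direction's radii and index share", {
  fi <- make_feature_inputs()
  seqs <- build_sequences(fi$stand, fi$profiles, fi$cpci,
                          direction_mode = "S", use_cpci = TRUE)
  i <- 2L
  prof <- fi$profiles[fi$profiles$tree_id == fi$stand$trees$tree_id[i] &
                        fi$profiles$direction == "S", ]
  expect_equal(seqs$y[i, ], prof$cr[-1], tolerance = 1e-12)
  share <- fi$cpci$cpci_S[fi$cpci$tree_id == fi$stand$trees$tree_id[i]]
  expect_equal(seqs$x[i, , "CPCI"], share, tolerance = 1e-12)
})

test_that("min-max normalizer maps train to [0,1] and inverts exactly", {
  fi <- make_feature_inputs()
  seqs <- build_sequences(fi$stand, fi$profiles, fi$cpci)
  parts <- split_dataset(seqs, seed = 1)
  nrm <- suppressWarnings(fit_normalizer(parts$train))
  tr <- transform_sequences(nrm, parts$train)
  expect_true(all(tr$x >= -1e-12 & tr$x <= 1 + 1e-12))
  expect_true(all(tr$y >= -1e-12 & tr$y <= 1 + 1e-12))
  expect_equal(inverse_transform_y(nrm, tr$y), parts$train$y,
               tolerance = 1e-12)
  # normalizer statistics come from the training partition only
  for (f in seq_along(nrm$x_min)) {
    expect_equal(nrm$x_min[f], min(parts$train$x[, , f]))
    expect_equal(nrm$x_max[f], max(parts$train$x[, , f]))
  }
  # a value above the training max transforms above 1 and is not clipped
  probe <- parts$val
  f_dbh <- match("DBH", probe$feature_names)
  probe$x[1, , f_dbh] <- nrm$x_max[f_dbh] * 2
  out <- transform_sequences(nrm, probe)
  expect_true(all(out$x[1, , f_dbh] > 1))
  # the basic three-point example
  toy <- seqs
  toy$x[, , 1] <- c(2, 4, 6)  # feature takes only these three values
  nrm2 <- suppressWarnings(fit_normalizer(toy))
  out2 <- transform_sequences(nrm2, toy)
  expect_equal(out2$x[1:3, 1, 1], c(0, 0.5, 1))
})

test_that("tree-level split respects ratios, determinism, and disjointness", {
  gen <- generate_stand(stand_params(n_trees = 100L), seed = 8L)
  stand <- apply_filters(gen$stand)$kept
  pr <- crown_profiles(stand)
  seqs <- build_sequences(stand, pr, NULL, use_cpci = FALSE)
  parts <- split_dataset(seqs, seed = 5)
  expect_equal(length(parts$train$tree_id), 80L)
  expect_equal(length(parts$val$tree_id), 10L)
  expect_equal(length(parts$test$tree_id), 10L)
  parts2 <- split_dataset(seqs, seed = 5)
  expect_identical(parts$train$tree_id, parts2$train$tree_id)
  all_ids <- c(parts$train$tree_id, parts$val$tree_id, parts$test$tree_id)
  expect_setequal(all_ids, seqs$tree_id)
  expect_equal(length(all_ids), length(unique(all_ids)))
  expect_error(split_dataset(seqs, ratios = c(0.7, 0.1, 0.1)), "sum to 1")
})
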