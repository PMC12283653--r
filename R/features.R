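#' Feature names of the full model input vector
#'
#' The 14 per-step input variables, in canonical order. `CH`, `CR_lag` and
#' `CPCI` vary across the 10 height-layer steps; the rest are static tree
#' or stand attributes repeated on every step. With `use_cpci = FALSE` the
#' final slot is dropped (13 features).
#' @return Character vector of length 14.
#' @export
feature_names <- function() {
  c("AGE", "DBH", "TH", "CW", "HCW", "HCB", "CH", "LCL", "TSC", "CLR",
    "BA", "SDI", "CR_lag", "CPCI")
}

#' Assemble per-tree feature sequences
#'
#' Builds, for every tree of a filtered stand, the ordered sequence of 10
#' height-layer steps used by the sequence models: at step k the input
#' vector holds the tree/stand attributes, the layer height
#' `CH_k = 0.1 * k * LCL`, the previous layer's crown radius `CR_lag`
#' (zero at the tree-top anchor), and the layer competition index; the
#' target is the layer's crown radius. In `"mean"` mode targets come from
#' the direction-averaged profile and the competition slot is `CPCI_k`;
#' in a directional mode they come from that direction's profile and its
#' allocated share of the index.
#'
#' A missing height-of-maximum-crown-width measurement is imputed with the
#' plot mean (it does not enter the competition geometry).
#'
#' @param stand A filtered `crown_stand`.
#' @param profiles Long profile table from [crown_profiles()].
#' @param cpci_table Competition table from [compute_cpci()]; may be NULL
#'   when `use_cpci = FALSE`.
#' @param direction_mode One of `"mean"`, `"E"`, `"W"`, `"S"`, `"N"`.
#' @param use_cpci Include the competition index as the 14th feature.
#' @param step_order `"top_down"` (default; the lag is anchored by the
#'   known zero radius at the tree top) or `"base_up"`.
#' @return An object of class `crown_sequences`: list with `x`
#'   (array `[n, 10, n_features]`), `y` (matrix `[n, 10]`, radii in m),
#'   `plot_id`, `tree_id`, `direction`, `feature_names`, `step_order`.
#' @export
build_sequences <- function(stand, profiles, cpci_table = NULL,
                            direction_mode = c("mean", "E", "W", "S", "N"),
                            use_cpci = TRUE,
                            step_order = c("top_down", "base_up")) {
  direction_mode <- match.arg(direction_mode)
  step_order <- match.arg(step_order)
  if (use_cpci && is.null(cpci_table)) {
    stop("use_cpci = TRUE requires a competition table")
  }
  tr <- stand$trees
  dv <- derive_variables(stand)
  # impute missing HCW with the plot mean
  hcw <- tr$hcw_m
  for (p in unique(tr$plot_id)) {
    sel <- tr$plot_id == p
    if (anyNA(hcw[sel])) {
      m <- mean(hcw[sel], na.rm = TRUE)
      if (!is.finite(m)) m <- 0
      hcw[sel][is.na(hcw[sel])] <- m
    }
  }
  prof_dir <- if (direction_mode == "mean") "MEAN" else direction_mode
  pr_key <- paste(profiles$plot_id, profiles$tree_id, profiles$direction,
                  sep = "\r")
  cp_col <- if (direction_mode == "mean") "cpci" else
    paste0("cpci_", direction_mode)
  if (use_cpci) {
    cp_key <- paste(cpci_table$plot_id, cpci_table$tree_id, sep = "\r")
  }
  fn <- feature_names()
  if (!use_cpci) fn <- fn[fn != "CPCI"]
  n <- nrow(tr)
  x <- array(NA_real_, c(n, N_LAYERS, length(fn)),
             dimnames = list(NULL, NULL, fn))
  y <- matrix(NA_real_, n, N_LAYERS)
  for (i in seq_len(n)) {
    key <- paste(tr$plot_id[i], tr$tree_id[i], sep = "\r")
    cr <- profiles$cr[pr_key == paste(key, prof_dir, sep = "\r")]
    if (length(cr) != 11L) {
      stop(sprintf("profile missing for tree %s", tr$tree_id[i]))
    }
    k <- if (step_order == "top_down") 1:10 else 10:1
    targets <- cr[-1][k]
    lag <- if (step_order == "top_down") c(0, targets[-10]) else
      c(0, targets[-10])
    ch <- 0.1 * k * dv$lcl[i]
    x[i, , "AGE"] <- tr$age_yr[i]
    x[i, , "DBH"] <- tr$dbh_cm[i]
    x[i, , "TH"] <- tr$th_m[i]
    x[i, , "CW"] <- tr$cw_m[i]
    x[i, , "HCW"] <- hcw[i]
    x[i, , "HCB"] <- tr$hcb_m[i]
    x[i, , "CH"] <- ch
    x[i, , "LCL"] <- dv$lcl[i]
    x[i, , "TSC"] <- dv$tsc[i]
    x[i, , "CLR"] <- dv$clr[i]
    x[i, , "BA"] <- dv$ba[i]
    x[i, , "SDI"] <- dv$sdi[i]
    x[i, , "CR_lag"] <- lag
    if (use_cpci) {
      cp <- cpci_table[[cp_col]][cp_key == key]
      if (length(cp) != 10L) {
        stop(sprintf("competition index missing for tree %s", tr$tree_id[i]))
      }
      x[i, , "CPCI"] <- cp[k]
    }
    y[i, ] <- targets
  }
  structure(list(x = x, y = y, plot_id = tr$plot_id, tree_id = tr$tree_id,
                 direction = direction_mode, feature_names = fn,
                 step_order = step_order),
            class = "crown_sequences")
}

#' @export
print.crown_sequences <- function(x, ...) {
  cat(sprintf("<crown_sequences> %d sequence(s) x %d steps x %d features (direction: %s)\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], x$direction))
  invisible(x)
}

subset_sequences <- function(seqs, idx) {
  structure(list(x = seqs$x[idx, , , drop = FALSE],
                 y = seqs$y[idx, , drop = FALSE],
                 plot_id = seqs$plot_id[idx], tree_id = seqs$tree_id[idx],
                 direction = seqs$direction,
                 feature_names = seqs$feature_names,
                 step_order = seqs$step_order),
            class = "crown_sequences")
}

#' Fit a min-max normalizer on training sequences
#'
#' Learns per-feature minima and maxima (and the target's) from the
#' training partition only, so the transform maps the training data into
#' `[0, 1]`. Validation/test values outside the training range transform
#' outside `[0, 1]` and are left unclipped (information-preserving). A
#' constant feature (max = min) is mapped to 0 with a warning.
#'
#' @param train A `crown_sequences` training partition.
#' @return An object of class `crown_normalizer`.
#' @export
fit_normalizer <- function(train) {
  stopifnot(inherits(train, "crown_sequences"))
  if (dim(train$x)[1] == 0L) stop("empty training partition")
  nf <- dim(train$x)[3]
  xmin <- xmax <- numeric(nf)
  for (f in seq_len(nf)) {
    v <- train$x[, , f]
    xmin[f] <- min(v); xmax[f] <- max(v)
  }
  if (any(xmax == xmin)) {
    warning(sprintf("constant feature(s) mapped to 0: %s",
                    paste(train$feature_names[xmax == xmin], collapse = ", ")),
            call. = FALSE)
  }
  structure(list(x_min = xmin, x_max = xmax,
                 y_min = min(train$y), y_max = max(train$y),
                 feature_names = train$feature_names),
            class = "crown_normalizer")
}

#' Apply a fitted normalizer to sequences
#' @param normalizer A `crown_normalizer` from [fit_normalizer()].
#' @param seqs A `crown_sequences` object.
#' @return The sequences with `x` and `y` min-max scaled.
#' @export
transform_sequences <- function(normalizer, seqs) {
  stopifnot(inherits(normalizer, "crown_normalizer"),
            inherits(seqs, "crown_sequences"))
  if (!identical(normalizer$feature_names, seqs$feature_names)) {
    stop("normalizer was fitted on a different feature set")
  }
  out <- seqs
  for (f in seq_along(normalizer$x_min)) {
    rng <- normalizer$x_max[f] - normalizer$x_min[f]
    out$x[, , f] <- if (rng > 0) {
      (seqs$x[, , f] - normalizer$x_min[f]) / rng
    } else 0
  }
  yr <- normalizer$y_max - normalizer$y_min
  out$y <- if (yr > 0) (seqs$y - normalizer$y_min) / yr else seqs$y * 0
  out
}

#' Map normalized predictions back to metres
#' @param normalizer A `crown_normalizer`.
#' @param y Normalized targets or predictions.
#' @return Values on the original scale (m).
#' @export
inverse_transform_y <- function(normalizer, y) {
  stopifnot(inherits(normalizer, "crown_normalizer"))
  y * (normalizer$y_max - normalizer$y_min) + normalizer$y_min
}

# Normalize a single radius value (used by autoregressive prediction).
transform_y <- function(normalizer, y) {
  yr <- normalizer$y_max - normalizer$y_min
  if (yr > 0) (y - normalizer$y_min) / yr else y * 0
}

#' Split sequences into train / validation / test partitions
#'
#' Tree-level random split: every sequence of a given tree lands in the
#' same partition, so the lag feature cannot leak information across
#' partitions. Partition sizes follow the ratios up to rounding; the split
#' is reproducible under `seed`.
#'
#' @param seqs A `crown_sequences` object.
#' @param ratios Train/validation/test fractions summing to 1
#'   (default 0.8/0.1/0.1).
#' @param seed Integer seed.
#' @return List of `crown_sequences`: `train`, `val`, `test`.
#' @export
split_dataset <- function(seqs, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(seqs, "crown_sequences"))
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  trees <- unique(paste(seqs$plot_id, seqs$tree_id, sep = "\r"))
  n <- length(trees)
  if (n < 10L) stop("at least 10 trees required for an 8:1:1 split")
  perm <- with_seed(seed, sample(n))
  counts <- diff(c(0L, round(cumsum(ratios) * n)))
  part <- rep(c("train", "val", "test"), counts)
  assignment <- stats::setNames(part, trees[perm])
  key <- paste(seqs$plot_id, seqs$tree_id, sep = "\r")
  lapply(stats::setNames(nm = c("train", "val", "test")), function(p) {
    subset_sequences(seqs, which(assignment[key] == p))
  })
}
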