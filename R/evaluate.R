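#' Evaluation metric suite
#'
#' The five goodness-of-fit statistics used throughout:
#' `MSE = mean((y - yhat)^2)` (m^2), `RMSE = sqrt(MSE)` (m),
#' `MAE = mean(|y - yhat|)` (m), `ME = mean(y - yhat)` (m), and
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Metrics are
#' computed on pooled records in metres (after reverse normalization).
#' If the observations have zero variance, R-squared is undefined and
#' reported as `NaN` with a warning.
#'
#' @param observed,predicted Equal-length numeric vectors (m).
#' @return One-row data.frame `mse, rmse, mae, me, r2, n`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 4))
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0L) {
    stop("observed and predicted must be nonempty and of equal length")
  }
  e <- observed - predicted
  mse <- mean(e^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in observed values; R2 undefined", call. = FALSE)
    NaN
  } else 1 - sum(e^2) / ss_tot
  data.frame(mse = mse, rmse = sqrt(mse), mae = mean(abs(e)), me = mean(e),
             r2 = r2, n = length(observed))
}

#' Condition-by-condition evaluation report
#'
#' Collects predictions from a set of evaluation conditions
#' (architecture x direction x with/without the competition index) into
#' the standard report table. Each entry of `results` is a list with
#' `arch`, `direction`, `use_cpci`, `observed`, `predicted`; entries whose
#' predictions are absent are reported with `NA` metrics rather than
#' failing.
#'
#' @param results List of condition entries (see Details).
#' @return data.frame `arch, direction, use_cpci, mse_m2, rmse_m, mae_m,
#'   me_m, r2, n`.
#' @export
evaluation_matrix <- function(results) {
  rows <- lapply(results, function(r) {
    base <- data.frame(arch = r$arch, direction = r$direction,
                       use_cpci = isTRUE(r$use_cpci),
                       stringsAsFactors = FALSE)
    if (is.null(r$predicted) || is.null(r$observed)) {
      cbind(base, data.frame(mse_m2 = NA_real_, rmse_m = NA_real_,
                             mae_m = NA_real_, me_m = NA_real_,
                             r2 = NA_real_, n = 0L))
    } else {
      m <- compute_metrics(as.numeric(r$observed), as.numeric(r$predicted))
      cbind(base, data.frame(mse_m2 = m$mse, rmse_m = m$rmse, mae_m = m$mae,
                             me_m = m$me, r2 = m$r2, n = m$n))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format an evaluation report as text
#'
#' Renders the report table with the best value per metric column (lowest
#' error, highest R-squared) marked with an asterisk.
#'
#' @param report A data.frame from [evaluation_matrix()].
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  metr <- c("mse_m2", "rmse_m", "mae_m", "me_m", "r2")
  best <- vapply(metr, function(m) {
    v <- report[[m]]
    if (all(is.na(v))) return(NA_integer_)
    if (m == "r2") which.max(replace(v, is.na(v), -Inf))
    else which.min(replace(abs(v), is.na(v), Inf))
  }, integer(1))
  lines <- sprintf("%-20s %-6s %-5s %s", "model", "dir", "CPCI",
                   paste(sprintf("%10s", metr), collapse = " "))
  for (i in seq_len(nrow(report))) {
    cells <- vapply(seq_along(metr), function(j) {
      v <- report[[metr[j]]][i]
      s <- if (is.na(v)) "--" else sprintf("%.5f", v)
      if (!is.na(best[j]) && best[j] == i) paste0(s, "*") else s
    }, character(1))
    lines <- c(lines, sprintf("%-20s %-6s %-5s %s", report$arch[i],
                              report$direction[i],
                              ifelse(report$use_cpci[i], "yes", "no"),
                              paste(sprintf("%10s", cells), collapse = " ")))
  }
  lines
}

#' Permutation feature importance
#'
#' Measures each input variable's contribution as the increase in test
#' MSE (in m^2, on the denormalized scale) when that variable's values are
#' shuffled across sequences, averaged over `n_repeats` shuffles. Static
#' tree attributes are shuffled with one permutation shared by all 10
#' steps (keeping within-tree consistency); step-varying features (CH,
#' the radius lag, the competition index) are shuffled independently per
#' step slot.
#'
#' @param model A trained `crown_model`.
#' @param dataset A held-out `crown_sequences` object (raw scale).
#' @param n_repeats Number of shuffles per feature (>= 1).
#' @param seed Integer seed.
#' @return data.frame `feature, importance, rank`, sorted by descending
#'   importance.
#' @export
permutation_importance <- function(model, dataset, n_repeats = 5L, seed = 1L) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  step_varying <- c("CH", "CR_lag", "CPCI")
  base_pred <- predict(model, dataset)
  base_mse <- mean((dataset$y - base_pred)^2)
  n <- dim(dataset$x)[1]
  fn <- dataset$feature_names
  imp <- with_seed(seed, {
    vapply(seq_along(fn), function(f) {
      deltas <- vapply(seq_len(n_repeats), function(rep) {
        perm_data <- dataset
        if (fn[f] %in% step_varying) {
          for (t in seq_len(dim(dataset$x)[2])) {
            perm_data$x[, t, f] <- dataset$x[sample(n), t, f]
          }
        } else {
          p <- sample(n)
          perm_data$x[, , f] <- dataset$x[p, , f]
        }
        pred <- predict(model, perm_data)
        mean((dataset$y - pred)^2) - base_mse
      }, numeric(1))
      mean(deltas)
    }, numeric(1))
  })
  out <- data.frame(feature = fn, importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
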