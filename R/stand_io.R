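#' Read a measured stand from delimited files
#'
#' Loads the three tables describing a measured stand: one row per tree
#' (`trees.csv`), the directional crown-radius measurements in long format
#' (`radii.csv`), and the plot descriptions (`plots.csv`). All files are
#' UTF-8 comma-separated with a mandatory header row and `.` as the decimal
#' separator.
#'
#' Expected columns:
#' \describe{
#'   \item{trees}{`plot_id, tree_id, x, y, dbh_cm, th_m, hcb_m, hcw_m, cw_m, age_yr`}
#'   \item{radii}{`plot_id, tree_id, direction, rch, cr_m` with
#'     `direction` in E/W/S/N}
#'   \item{plots}{`plot_id, radius_m, slope_deg, aspect`}
#' }
#'
#' Coordinates are plot-local Cartesian metres with the plot centre at the
#' origin and y pointing to geographic north. Malformed rows (non-numeric
#' measurements, unknown direction codes) are dropped with a warning that
#' reports their row numbers; a missing mandatory column is an error.
#'
#' @param trees,radii,plots Paths to the three CSV files.
#' @return An object of class `crown_stand`: a list with data.frames
#'   `trees`, `radii` and `plots`.
#' @seealso [write_stand()], [apply_filters()], [derive_variables()]
#' @export
read_stand <- function(trees, radii, plots) {
  tr <- read_checked(trees,
    cols = c("plot_id", "tree_id", "x", "y", "dbh_cm", "th_m", "hcb_m",
             "hcw_m", "cw_m", "age_yr"),
    numeric_cols = c("x", "y", "dbh_cm", "th_m", "hcb_m", "cw_m", "age_yr"))
  # hcw_m may be missing (imputed later); coerce but allow NA
  tr$hcw_m <- suppressWarnings(as.numeric(tr$hcw_m))
  rd <- read_checked(radii,
    cols = c("plot_id", "tree_id", "direction", "rch", "cr_m"),
    numeric_cols = c("rch", "cr_m"))
  bad_dir <- !(rd$direction %in% DIRECTIONS)
  if (any(bad_dir)) {
    warning(sprintf("radii: dropping %d row(s) with unknown direction (rows %s)",
                    sum(bad_dir), paste(which(bad_dir), collapse = ", ")))
    rd <- rd[!bad_dir, , drop = FALSE]
  }
  pl <- read_checked(plots,
    cols = c("plot_id", "radius_m", "slope_deg", "aspect"),
    numeric_cols = c("radius_m", "slope_deg"))
  if (any(pl$radius_m <= 0)) stop("plots: radius_m must be > 0")
  new_stand(tr, rd, pl)
}

new_stand <- function(trees, radii, plots) {
  structure(list(trees = trees, radii = radii, plots = plots),
            class = "crown_stand")
}

#' @export
print.crown_stand <- function(x, ...) {
  cat(sprintf("<crown_stand> %d tree(s) in %d plot(s); %d crown-radius measurement(s)\n",
              nrow(x$trees), nrow(x$plots), nrow(x$radii)))
  invisible(x)
}

read_checked <- function(path, cols, numeric_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing mandatory column(s): %s",
                 basename(path), paste(missing, collapse = ", ")))
  }
  df <- df[cols]
  bad <- rep(FALSE, nrow(df))
  for (nc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[nc]]))
    bad <- bad | (is.na(v) & !is.na(df[[nc]]))
    df[[nc]] <- v
  }
  if (any(bad)) {
    warning(sprintf("%s: dropping %d malformed row(s) (rows %s)",
                    basename(path), sum(bad),
                    paste(which(bad), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a stand back to delimited files
#'
#' Inverse of [read_stand()]: emits `trees.csv`, `radii.csv` and `plots.csv`
#' into `dir` in the documented schema, so that reading them back
#' reproduces the stand.
#'
#' @param stand A `crown_stand`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_stand <- function(stand, dir) {
  stopifnot(inherits(stand, "crown_stand"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("trees.csv", "radii.csv", "plots.csv"))
  utils::write.csv(stand$trees, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(stand$radii, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(stand$plots, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Data-quality filters for measured trees
#'
#' Applies the measurement-protocol exclusion rules: a tree is rejected if
#' any of its crown-radius measurements sits at a relative crown height
#' above 1.0 (`rch_gt_1`), or if any cardinal direction carries fewer than
#' four valid radius values (`lt_4_radii`). Additional validity guards
#' reject trees with more than four radii in a direction (`gt_4_radii`),
#' with a breast-height diameter below the 5 cm calipering threshold
#' (`dbh_lt_5`), or with a crown base at or above the tree top
#' (`hcb_ge_th`). A radius value is valid when it is finite, nonnegative
#' and its relative crown height lies in (0, 1].
#'
#' Filtering is idempotent: applying it to the kept stand rejects nothing.
#'
#' @param stand A `crown_stand` from [read_stand()] or [generate_stand()].
#' @return A list with `kept` (a `crown_stand` restricted to accepted
#'   trees) and `rejected` (data.frame `plot_id, tree_id, reason`).
#' @export
apply_filters <- function(stand) {
  stopifnot(inherits(stand, "crown_stand"))
  tr <- stand$trees
  rd <- stand$radii
  key <- function(p, t) paste(p, t, sep = "\r")
  rd_key <- key(rd$plot_id, rd$tree_id)
  reasons <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    rows <- rd[rd_key == key(tr$plot_id[i], tr$tree_id[i]), , drop = FALSE]
    reason <- NA_character_
    if (tr$dbh_cm[i] < 5) {
      reason <- "dbh_lt_5"
    } else if (tr$hcb_m[i] >= tr$th_m[i]) {
      reason <- "hcb_ge_th"
    } else if (any(rows$rch > 1 + 1e-9, na.rm = TRUE)) {
      reason <- "rch_gt_1"
    } else {
      valid <- is.finite(rows$rch) & is.finite(rows$cr_m) &
        rows$rch > 0 & rows$rch <= 1 + 1e-9 & rows$cr_m >= 0
      counts <- vapply(DIRECTIONS, function(d) sum(valid & rows$direction == d),
                       integer(1))
      if (any(counts < 4L)) reason <- "lt_4_radii"
      else if (any(counts > 4L)) reason <- "gt_4_radii"
    }
    reasons[i] <- reason
  }
  keep <- is.na(reasons)
  kept_trees <- tr[keep, , drop = FALSE]
  kept_key <- key(kept_trees$plot_id, kept_trees$tree_id)
  kept_radii <- rd[rd_key %in% kept_key, , drop = FALSE]
  rownames(kept_trees) <- rownames(kept_radii) <- NULL
  list(
    kept = new_stand(kept_trees, kept_radii, stand$plots),
    rejected = data.frame(plot_id = tr$plot_id[!keep],
                          tree_id = tr$tree_id[!keep],
                          reason = reasons[!keep],
                          stringsAsFactors = FALSE)
  )
}

#' Derived tree and stand variables
#'
#' Computes, per tree, the derived dendrometric variables used as model
#' features:
#' \describe{
#'   \item{LCL}{largest crown length, `TH - HCB` (m);}
#'   \item{CLR}{crown length ratio, `LCL / TH`;}
#'   \item{TSC}{tree slenderness coefficient, `TH` (m) over `DBH` (cm);}
#'   \item{BA}{plot basal area per hectare, `sum(pi * (DBH/200)^2) / area_ha`
#'     (m^2/ha);}
#'   \item{SDI}{Reineke stand density index,
#'     `N_ha * (Dg / 25)^1.605` with `Dg` the quadratic mean diameter (cm).}
#' }
#' Plot area for per-hectare scaling is `pi * radius_m^2` (circular plots).
#' BA and SDI are plot-level quantities repeated on every tree of the plot.
#'
#' @param stand A filtered `crown_stand`.
#' @return data.frame with columns `plot_id, tree_id, lcl, clr, tsc, ba, sdi`.
#' @export
derive_variables <- function(stand) {
  stopifnot(inherits(stand, "crown_stand"))
  tr <- stand$trees
  if (any(tr$th_m <= tr$hcb_m)) {
    bad <- which(tr$th_m <= tr$hcb_m)
    stop(sprintf("invalid tree(s): TH <= HCB (rows %s)",
                 paste(bad, collapse = ", ")))
  }
  lcl <- tr$th_m - tr$hcb_m
  out <- data.frame(plot_id = tr$plot_id, tree_id = tr$tree_id,
                    lcl = lcl, clr = lcl / tr$th_m, tsc = tr$th_m / tr$dbh_cm,
                    ba = NA_real_, sdi = NA_real_, stringsAsFactors = FALSE)
  for (p in unique(tr$plot_id)) {
    in_plot <- tr$plot_id == p
    r <- stand$plots$radius_m[match(p, stand$plots$plot_id)]
    if (is.na(r)) stop(sprintf("plot '%s' absent from plots table", p))
    area_ha <- pi * r^2 / 1e4
    ba <- sum(pi * (tr$dbh_cm[in_plot] / 200)^2) / area_ha
    n_ha <- sum(in_plot) / area_ha
    dg <- sqrt(mean(tr$dbh_cm[in_plot]^2))
    out$ba[in_plot] <- ba
    out$sdi[in_plot] <- n_ha * (dg / 25)^1.605
  }
  out
}
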