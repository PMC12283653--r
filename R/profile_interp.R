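#' Interpolate a directional crown profile onto the uniform grid
#'
#' Regularizes one tree-direction's measured crown radii onto the uniform
#' 11-point relative-crown-height (RCH) grid `0, 0.1, ..., 1.0` using
#' shape-preserving piecewise cubic Hermite interpolation (PCHIP). The
#' known zero-radius anchor at the tree top (RCH = 0, CR = 0) is prepended
#' before interpolation, so the profile always starts at zero. PCHIP
#' reproduces the measured knots exactly, is monotone on monotone data
#' segments, and never overshoots local data extrema, which is why it is
#' preferred over Lagrange/Newton/cubic-spline interpolants for crown
#' profiles.
#'
#' @param rch Measured relative crown heights, strictly increasing, in
#'   (0, 1]. At least four values.
#' @param cr Measured crown radii (m), nonnegative, same length as `rch`.
#' @param rch_out Evaluation points in `[0, 1]`; defaults to the uniform
#'   11-point grid.
#' @param include_top_zero Prepend the (0, 0) tree-top anchor (default TRUE).
#' @return Numeric vector of interpolated radii at `rch_out`.
#' @examples
#' interpolate_profile(c(0.25, 0.5, 0.75, 1), c(0.5, 1, 1.5, 2))
#' @export
interpolate_profile <- function(rch, cr, rch_out = RCH_GRID,
                                include_top_zero = TRUE) {
  if (length(rch) != length(cr)) stop("rch and cr must have equal length")
  if (length(rch) < 4L) stop("fewer than 4 measured pairs")
  if (anyDuplicated(rch)) stop("duplicate RCH values")
  if (any(!is.finite(rch)) || any(!is.finite(cr))) stop("non-finite input")
  if (any(cr < 0)) stop("negative crown radius")
  if (any(rch <= 0) || any(rch > 1 + 1e-9)) stop("RCH must lie in (0, 1]")
  o <- order(rch)
  rch <- rch[o]; cr <- cr[o]
  if (include_top_zero) {
    rch <- c(0, rch)
    cr <- c(0, cr)
  }
  if (any(rch_out < min(rch) - 1e-9) || any(rch_out > max(rch) + 1e-9)) {
    stop("evaluation outside the measured RCH range (no extrapolation)")
  }
  out <- pracma::pchip(rch, cr, pmin(pmax(rch_out, min(rch)), max(rch)))
  if (any(out < 0)) {
    # PCHIP cannot undershoot below local minima, so this should not fire;
    # clip defensively and report if it ever does.
    warning("interpolated radii below 0 were clipped", call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' Mean crown profile over the four directions
#'
#' The traditional direction-free profile: the arithmetic mean of the four
#' directional radii at each grid layer.
#'
#' @param profiles A list or matrix of the four directional profiles on a
#'   shared grid: either a list of equal-length numeric vectors or a
#'   matrix with one column per direction.
#' @return Numeric vector of per-layer mean radii.
#' @export
mean_profile <- function(profiles) {
  if (is.list(profiles)) {
    len <- vapply(profiles, length, integer(1))
    if (length(unique(len)) != 1L) stop("profiles have mismatched grids")
    profiles <- do.call(cbind, profiles)
  }
  rowMeans(profiles)
}

#' Interpolate every tree of a stand
#'
#' Runs [interpolate_profile()] for each tree and cardinal direction of a
#' filtered stand and appends the direction-averaged profile (`MEAN`).
#'
#' @param stand A filtered `crown_stand`.
#' @return data.frame in long format: `plot_id, tree_id, direction, rch, cr`
#'   with `direction` in E/W/S/N/MEAN and 11 rows per tree-direction.
#' @export
crown_profiles <- function(stand) {
  stopifnot(inherits(stand, "crown_stand"))
  tr <- stand$trees
  rd <- stand$radii
  rd_key <- paste(rd$plot_id, rd$tree_id, sep = "\r")
  res <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    rows <- rd[rd_key == paste(tr$plot_id[i], tr$tree_id[i], sep = "\r"), ,
               drop = FALSE]
    mat <- sapply(DIRECTIONS, function(d) {
      sel <- rows$direction == d
      interpolate_profile(rows$rch[sel], rows$cr_m[sel])
    })
    mat <- cbind(mat, MEAN = rowMeans(mat))
    res[[i]] <- data.frame(
      plot_id = tr$plot_id[i], tree_id = tr$tree_id[i],
      direction = rep(colnames(mat), each = length(RCH_GRID)),
      rch = rep(RCH_GRID, ncol(mat)),
      cr = as.vector(mat), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
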