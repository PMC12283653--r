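#' Vertical layer gate for crown competition
#'
#' Two crown layers compete only when their heights from the tree top
#' differ by at most `threshold` metres (default 2 m).
#'
#' @param ch_i,ch_j Crown heights from the treetop (m), nonnegative;
#'   vectorized.
#' @param threshold Gate width in metres.
#' @return Logical vector: TRUE where the pair is gated in.
#' @export
layer_gate <- function(ch_i, ch_j, threshold = 2) {
  if (any(ch_i < 0) || any(ch_j < 0)) stop("crown heights must be nonnegative")
  abs(ch_i - ch_j) <= threshold
}

#' Overlap area of two crown discs
#'
#' Area of intersection of two circles of radii `r1`, `r2` whose centres
#' (the two stems) are `d` apart, covering the three regimes: disjoint
#' (zero), partial overlap (circular lens: two circular-sector terms minus
#' twice the triangle area from Heron's formula), and containment (the
#' smaller disc's full area). Vectorized; symmetric in the radii;
#' continuous across the regime boundaries.
#'
#' @param r1,r2 Crown radii (m), nonnegative.
#' @param d Horizontal stem-to-stem distance (m), nonnegative.
#' @return Overlap areas (m^2).
#' @examples
#' pair_overlap_area(1, 1, 2)          # tangent: 0
#' pair_overlap_area(1, 0.5, 0.1)      # contained: pi * 0.25
#' pair_overlap_area(1, 1, 1)          # lens: 2*pi/3 - sqrt(3)/2
#' @export
pair_overlap_area <- function(r1, r2, d) {
  n <- max(length(r1), length(r2), length(d))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n); d <- rep_len(d, n)
  if (any(r1 < 0) || any(r2 < 0) || any(d < 0)) {
    stop("radii and distance must be nonnegative")
  }
  out <- numeric(n)
  rmin <- pmin(r1, r2)
  tol <- 1e-12
  contained <- d <= abs(r1 - r2) + tol
  disjoint <- d >= r1 + r2 - tol & !contained
  lens <- !contained & !disjoint
  out[contained] <- pi * rmin[contained]^2
  if (any(lens)) {
    a <- r1[lens]; b <- r2[lens]; dd <- d[lens]
    clamp <- function(x) pmin(pmax(x, -1), 1)
    t1 <- acos(clamp((a^2 + dd^2 - b^2) / (2 * dd * a))) * a^2
    t2 <- acos(clamp((b^2 + dd^2 - a^2) / (2 * dd * b))) * b^2
    p <- (a + b + dd) / 2
    tri <- sqrt(pmax(p * (p - a) * (p - b) * (p - dd), 0))
    out[lens] <- t1 + t2 - 2 * tri
  }
  out
}

#' Total crown overlap area of one subject layer
#'
#' Sums the disc-overlap area between layer `k` of the subject tree and
#' every layer of every Voronoi competitor, counting only layer pairs that
#' pass the vertical gate. Competitor layers with zero radius contribute
#' nothing.
#'
#' @param subject List with numeric vectors `ch` and `cr` (length 10,
#'   layers k = 1..10, heights from the treetop in m, radii in m).
#' @param competitors List of competitor descriptions, each a list with
#'   `ch`, `cr` (length 10) and scalar `dist` (stem distance, m).
#' @param k Subject layer index in 1..10.
#' @param gate Vertical gate width (m).
#' @return Total overlap area AO_i(k) in m^2.
#' @export
total_overlap <- function(subject, competitors, k, gate = 2) {
  sum_pairs(subject, competitors, k, gate)$ao
}

sum_pairs <- function(subject, competitors, k, gate = 2) {
  ao <- 0
  weighted <- 0
  ch_ik <- subject$ch[k]
  cr_ik <- subject$cr[k]
  for (comp in competitors) {
    ok <- layer_gate(ch_ik, comp$ch, gate) & comp$cr > 0
    if (!any(ok)) next
    a <- pair_overlap_area(cr_ik, comp$cr[ok], comp$dist)
    ao <- ao + sum(a)
    if (cr_ik > 0 && ch_ik > 0) {
      weighted <- weighted +
        sum(a * (comp$ch[ok] * comp$cr[ok]) / (ch_ik * cr_ik))
    }
  }
  list(ao = ao, weighted = weighted)
}

#' Crown Profile Competition Index for one layer
#'
#' The layered competition index: each gated competitor layer's overlap
#' area with subject layer `k` is weighted by the competitor/subject size
#' ratio `(CH_jt * CR_jt) / (CH_ik * CR_ik)`, summed, and scaled by the
#' subject's crown projection area at that layer, `Z_ik = pi * CR_ik^2`.
#' A layer with zero subject radius has no crown disc and returns 0.
#'
#' @inheritParams total_overlap
#' @return CPCI_k (dimensionless, nonnegative).
#' @export
cpci <- function(subject, competitors, k, gate = 2) {
  cr_ik <- subject$cr[k]
  if (cr_ik <= 0) return(0)
  w <- sum_pairs(subject, competitors, k, gate)$weighted
  w / (pi * cr_ik^2)
}

#' Directional allocation of the layer competition index
#'
#' Splits a layer's CPCI across the four cardinal directions, giving
#' directions with a smaller crown radius a larger share:
#' `share_dir = CPCI_k * (1 - CR_dir / sum(CR_dir))`. The four shares
#' always sum to `3 * CPCI_k`. When all four radii are zero the shares
#' are all zero.
#'
#' @param cpci_k Layer competition index (scalar).
#' @param radii Named numeric vector of the four directional radii at the
#'   layer (order E, W, S, N if unnamed).
#' @return Named numeric vector of directional shares.
#' @export
directional_cpci <- function(cpci_k, radii) {
  if (length(radii) != 4L) stop("four directional radii required")
  if (any(radii < 0)) stop("negative directional radius")
  if (is.null(names(radii))) names(radii) <- DIRECTIONS
  s <- sum(radii)
  if (s == 0) {
    return(stats::setNames(numeric(4), names(radii)))
  }
  cpci_k * (1 - radii / s)
}

#' Compute the competition table for a whole stand
#'
#' Runs the full layered competition pipeline for every tree of a filtered
#' stand: Voronoi competitor determination (per plot), per-layer overlap
#' areas against all competitors, the layer competition index CPCI_k from
#' the direction-averaged (MEAN) profiles, and its directional allocation
#' from the directional radii.
#'
#' Layer heights are `CH_k = 0.1 * k * LCL` (heights from the treetop,
#' k = 1..10); geometry is computed once on the MEAN profiles and the
#' resulting CPCI_k is allocated across directions, so directional values
#' share the MEAN-based geometry.
#'
#' @param stand A filtered `crown_stand`.
#' @param profiles Long profile table from [crown_profiles()].
#' @param gate Vertical gate width (m), default 2.
#' @return data.frame `plot_id, tree_id, layer_k, rch, ao_m2, z_m2, cpci,
#'   cpci_E, cpci_W, cpci_S, cpci_N` with 10 rows per tree.
#' @export
compute_cpci <- function(stand, profiles, gate = 2) {
  stopifnot(inherits(stand, "crown_stand"))
  tr <- stand$trees
  dv <- derive_variables(stand)
  pr_key <- paste(profiles$plot_id, profiles$tree_id, profiles$direction,
                  sep = "\r")
  get_prof <- function(p, t, d) {
    v <- profiles$cr[pr_key == paste(p, t, d, sep = "\r")]
    if (length(v) != 11L) {
      stop(sprintf("profile missing for tree %s/%s direction %s", p, t, d))
    }
    v[-1] # layers 1..10
  }
  out <- vector("list", nrow(tr))
  idx <- 0L
  for (p in unique(tr$plot_id)) {
    rows <- which(tr$plot_id == p)
    pos <- cbind(tr$x[rows], tr$y[rows])
    plot_radius <- stand$plots$radius_m[match(p, stand$plots$plot_id)]
    nb <- voronoi_neighbors(pos, plot_radius)$neighbors
    lcl <- dv$lcl[rows]
    prof_mean <- lapply(seq_along(rows), function(i) {
      get_prof(p, tr$tree_id[rows[i]], "MEAN")
    })
    prof_dir <- lapply(seq_along(rows), function(i) {
      sapply(DIRECTIONS, function(d) get_prof(p, tr$tree_id[rows[i]], d))
    })
    ch <- lapply(seq_along(rows), function(i) 0.1 * (1:10) * lcl[i])
    for (i in seq_along(rows)) {
      comp <- lapply(nb[[i]], function(j) {
        list(ch = ch[[j]], cr = prof_mean[[j]],
             dist = sqrt(sum((pos[i, ] - pos[j, ])^2)))
      })
      subject <- list(ch = ch[[i]], cr = prof_mean[[i]])
      ao <- numeric(10); cp <- numeric(10)
      for (k in 1:10) {
        s <- sum_pairs(subject, comp, k, gate)
        ao[k] <- s$ao
        cp[k] <- if (subject$cr[k] > 0) s$weighted / (pi * subject$cr[k]^2) else 0
      }
      shares <- t(vapply(1:10, function(k) {
        directional_cpci(cp[k], prof_dir[[i]][k, ])
      }, numeric(4)))
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        plot_id = p, tree_id = tr$tree_id[rows[i]], layer_k = 1:10,
        rch = RCH_GRID[-1], ao_m2 = ao, z_m2 = pi * subject$cr^2, cpci = cp,
        cpci_E = shares[, "E"], cpci_W = shares[, "W"],
        cpci_S = shares[, "S"], cpci_N = shares[, "N"],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
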