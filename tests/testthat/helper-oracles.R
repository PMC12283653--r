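# Independent oracles used across the suite.

# Monte-Carlo estimate of the intersection area of two circles (radii r1, r2,
# centres d apart) by uniform sampling of the bounding box of the smaller
# circle (any intersection point lies inside both circles, hence inside the
# smaller one's bounding box).
mc_overlap_area <- function(r1, r2, d, n_samples = 1e6, chunk = 1e6) {
  # place circle 1 at origin, circle 2 at (d, 0); sample the smaller circle
  if (r2 < r1) {
    cx <- if (TRUE) d else 0
    # sample around circle 2
    cxs <- d; rs <- r2
  } else {
    cxs <- 0; rs <- r1
  }
  if (rs == 0) return(0)
  hits <- 0
  left <- n_samples
  while (left > 0) {
    m <- min(chunk, left)
    x <- stats::runif(m, cxs - rs, cxs + rs)
    y <- stats::runif(m, -rs, rs)
    hits <- hits + sum(x^2 + y^2 <= r1^2 & (x - d)^2 + y^2 <= r2^2)
    left <- left - m
  }
  (2 * rs)^2 * hits / n_samples
}

# Brute-force Voronoi adjacency oracle: pair (i, j) is adjacent iff some
# point of the plane (inside the plot circle) is closer to both i and j than
# to every other stem. A dense grid over the plot detects all but the
# thinnest shared edges; pairs on which the grid disagrees with `claimed`
# are re-examined by dense sampling along the (i, j) bisector chord, which
# resolves edges down to sub-millimetre length.
voronoi_grid_oracle <- function(pos, plot_radius, claimed, ngrid = 400,
                                refine_samples = 2e5) {
  n <- nrow(pos)
  g <- seq(-plot_radius, plot_radius, length.out = ngrid)
  pts <- as.matrix(expand.grid(x = g, y = g))
  pts <- pts[pts[, 1]^2 + pts[, 2]^2 <= plot_radius^2, , drop = FALSE]
  D <- outer(pts[, 1], pos[, 1], "-")^2 + outer(pts[, 2], pos[, 2], "-")^2
  nearest <- max.col(-D)
  D[cbind(seq_len(nrow(D)), nearest)] <- Inf
  second <- max.col(-D)
  adj <- matrix(FALSE, n, n)
  adj[cbind(nearest, second)] <- TRUE
  adj <- adj | t(adj)
  disputed <- which((adj != claimed) & upper.tri(adj), arr.ind = TRUE)
  for (r in seq_len(nrow(disputed))) {
    i <- disputed[r, 1]; j <- disputed[r, 2]
    adj[i, j] <- adj[j, i] <-
      bisector_edge_exists(pos, plot_radius, i, j, refine_samples)
  }
  adj
}

# TRUE iff the (i, j) Voronoi edge has positive length: some point on the
# perpendicular bisector, inside the plot circle, has no stem closer than
# i and j.
bisector_edge_exists <- function(pos, plot_radius, i, j, n_samples = 2e5) {
  mid <- (pos[i, ] + pos[j, ]) / 2
  u <- pos[j, ] - pos[i, ]
  u <- u / sqrt(sum(u^2))
  perp <- c(-u[2], u[1])
  # intersect the bisector line with the plot circle
  b <- sum(mid * perp)
  cc <- sum(mid^2) - plot_radius^2
  disc <- b^2 - cc
  if (disc <= 0) return(FALSE)
  tt <- seq(-b - sqrt(disc), -b + sqrt(disc), length.out = n_samples)
  px <- mid[1] + tt * perp[1]
  py <- mid[2] + tt * perp[2]
  di <- (px - pos[i, 1])^2 + (py - pos[i, 2])^2
  others <- setdiff(seq_len(nrow(pos)), c(i, j))
  ok <- rep(TRUE, length(tt))
  for (o in others) {
    ok <- ok & ((px - pos[o, 1])^2 + (py - pos[o, 2])^2 > di + 1e-12)
    if (!any(ok)) return(FALSE)
  }
  any(ok)
}

# Random stem configuration inside a plot circle with a soft minimum spacing.
random_positions <- function(n, plot_radius, min_spacing = 1) {
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  while (placed < n) {
    r <- plot_radius * sqrt(stats::runif(1)) * 0.97
    a <- stats::runif(1, 0, 2 * pi)
    cand <- c(r * cos(a), r * sin(a))
    if (placed == 0L ||
        min((pos[seq_len(placed), 1] - cand[1])^2 +
            (pos[seq_len(placed), 2] - cand[2])^2) >= min_spacing^2) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  pos
}

# Small filtered synthetic stand shared by several tests.
make_test_stand <- function(n_trees = 40L, seed = 7L, gamma = 0.4) {
  gen <- generate_stand(stand_params(n_trees = n_trees, gamma = gamma),
                        seed = seed)
  apply_filters(gen$stand)$kept
}

claimed_adjacency <- function(pos, plot_radius) {
  nb <- voronoi_neighbors(pos, plot_radius)$neighbors
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, nb[[i]]] <- TRUE
  adj
}
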