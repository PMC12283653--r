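#' Voronoi competitor determination
#'
#' Determines each tree's competitors as the trees whose Voronoi cells
#' share an edge of positive length with its own cell, after clipping all
#' cells to the circular plot boundary. Cells are built by successive
#' half-plane clipping of the (polygonized) plot disc with the
#' perpendicular bisectors of the subject and every other stem, visiting
#' candidates in order of increasing distance and stopping once the
#' bisector can no longer intersect the current cell. Each surviving cell
#' edge carries the identity of the stem whose bisector created it, which
#' yields the adjacency directly; the relation is symmetrized (a shared
#' edge detected from either side is a true Voronoi edge).
#'
#' With fewer than three stems, or all stems collinear, cell adjacency is
#' degenerate; a warning (class `crownprof_degenerate_geometry`) is issued
#' and every other tree is returned as a neighbor.
#'
#' @param positions Two-column matrix of stem coordinates (m), plot-local
#'   Cartesian with the plot centre at the origin.
#' @param plot_radius Plot radius (m); cells are clipped to this circle.
#' @param n_circle Number of segments used to polygonize the plot boundary.
#' @return List with `neighbors` (per tree, an integer vector of row
#'   indices into `positions`) and `cells` (per tree, the clipped cell
#'   polygon as a two-column matrix of vertices).
#' @export
voronoi_neighbors <- function(positions, plot_radius, n_circle = 128L) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("positions must be a two-column matrix")
  n <- nrow(positions)
  if (n < 3L || is_collinear(positions)) {
    warning(structure(
      class = c("crownprof_degenerate_geometry", "warning", "condition"),
      list(message = "fewer than 3 non-collinear stems; treating all other trees as neighbors",
           call = sys.call())))
    nb <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
    return(list(neighbors = nb, cells = vector("list", n)))
  }
  theta <- seq(0, 2 * pi, length.out = n_circle + 1L)[-(n_circle + 1L)]
  circle <- cbind(plot_radius * cos(theta), plot_radius * sin(theta))
  d2 <- as.matrix(stats::dist(positions))^2
  adj <- matrix(FALSE, n, n)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    V <- circle
    lab <- integer(nrow(V)) # 0 = plot boundary
    ord <- order(d2[i, ])
    ord <- ord[ord != i]
    for (j in ord) {
      # the bisector of (i, j) lies at distance d_ij / 2 from stem i; once
      # that exceeds the cell's farthest vertex, no later candidate can cut
      maxv2 <- max((V[, 1] - positions[i, 1])^2 + (V[, 2] - positions[i, 2])^2)
      if (d2[i, j] / 4 > maxv2) break
      a <- positions[j, ] - positions[i, ]
      b <- sum(a * (positions[i, ] + positions[j, ]) / 2)
      clipped <- clip_halfplane(V, lab, a, b, j)
      V <- clipped$V
      lab <- clipped$lab
      if (nrow(V) < 3L) break
    }
    cells[[i]] <- V
    if (nrow(V) >= 3L) {
      nxt <- c(seq_len(nrow(V))[-1], 1L)
      len <- sqrt((V[nxt, 1] - V[, 1])^2 + (V[nxt, 2] - V[, 2])^2)
      js <- unique(lab[lab > 0L & len > 1e-9])
      adj[i, js] <- TRUE
    }
  }
  adj <- adj | t(adj)
  list(neighbors = lapply(seq_len(n), function(i) which(adj[i, ])),
       cells = cells)
}

is_collinear <- function(positions) {
  centred <- sweep(positions, 2, colMeans(positions))
  s <- svd(centred, nu = 0, nv = 0)$d
  s[2] <= 1e-9 * max(s[1], 1)
}

# Clip convex polygon V (vertices in order; edge e starts at vertex e) by the
# half-plane {x : a.x <= b}; edges created on the clip line get label j.
clip_halfplane <- function(V, lab, a, b, j) {
  n <- nrow(V)
  s <- V %*% a - b
  tol <- 1e-12 * max(abs(b), 1)
  ins <- s <= tol
  if (all(ins)) return(list(V = V, lab = lab))
  if (!any(ins)) return(list(V = V[0, , drop = FALSE], lab = integer(0)))
  outV <- matrix(NA_real_, n + 2L, 2L)
  outL <- integer(n + 2L)
  m <- 0L
  for (e in seq_len(n)) {
    e2 <- if (e == n) 1L else e + 1L
    if (ins[e]) {
      m <- m + 1L
      outV[m, ] <- V[e, ]
      outL[m] <- lab[e]
      if (!ins[e2]) {
        # leaving: intersection point starts the new edge along the clip line
        t <- s[e] / (s[e] - s[e2])
        m <- m + 1L
        outV[m, ] <- V[e, ] + t * (V[e2, ] - V[e, ])
        outL[m] <- j
      }
    } else if (ins[e2]) {
      # entering: intersection point resumes the original edge
      t <- s[e] / (s[e] - s[e2])
      m <- m + 1L
      outV[m, ] <- V[e, ] + t * (V[e2, ] - V[e, ])
      outL[m] <- lab[e]
    }
  }
  list(V = outV[seq_len(m), , drop = FALSE], lab = outL[seq_len(m)])
}
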