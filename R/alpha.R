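# Alpha-shape concave hull.
#
# The alpha complex retains the Delaunay triangles whose circumradius is at
# most the disk radius alpha; the alpha shape is the union of those
# triangles. This is the standard alpha-complex realisation of the
# "disks of radius alpha carve the boundary" description, and it reduces to
# the convex hull as alpha grows large.

# Extract boundary rings of a union of CCW triangles. Boundary edges are
# directed edges whose reverse is not present; following them with the
# interior kept on the left yields CCW outer rings and CW hole rings.
tri_union_boundary <- function(pts, tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  fwd <- paste(e[, 1], e[, 2])
  rev_ <- paste(e[, 2], e[, 1])
  bnd <- e[!(fwd %in% rev_), , drop = FALSE]
  if (nrow(bnd) == 0) return(list())
  rings <- list()
  used <- rep(FALSE, nrow(bnd))
  # index boundary edges by start vertex
  starts <- split(seq_len(nrow(bnd)), bnd[, 1])
  repeat {
    s <- which(!used)[1]
    if (is.na(s)) break
    ring <- bnd[s, 1]
    cur <- s
    repeat {
      used[cur] <- TRUE
      nxt_v <- bnd[cur, 2]
      cand <- starts[[as.character(nxt_v)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      if (length(cand) > 1) {
        # pinch vertex: take the next edge clockwise from the reverse of
        # the incoming edge (standard left-face traversal rule)
        vin <- pts[bnd[cur, 1], ] - pts[nxt_v, ]
        a_in <- atan2(vin[2], vin[1])
        angs <- vapply(cand, function(ci) {
          vout <- pts[bnd[ci, 2], ] - pts[nxt_v, ]
          a <- a_in - atan2(vout[2], vout[1])
          a %% (2 * pi)
        }, 0)
        cand <- cand[which.min(angs)]
      }
      ring <- c(ring, nxt_v)
      cur <- cand
      if (bnd[cur, 1] == ring[1] && used[cur]) break
    }
    # close: drop trailing vertex if it repeats the head
    if (length(ring) >= 2 && ring[length(ring)] == ring[1])
      ring <- ring[-length(ring)]
    if (length(ring) >= 3)
      rings[[length(rings) + 1]] <- pts[ring, , drop = FALSE]
  }
  rings
}

#' Alpha-shape concave hull of a point set
#'
#' Computes the union of Delaunay triangles whose circumradius is at most
#' \code{alpha}. Returns a polygon or multipolygon \code{\link{fgeom}}; the
#' kept triangle index matrix is attached as attribute \code{"triangles"}
#' and the covered point indices as \code{"covered"}. Points whose incident
#' triangles are all rejected by the alpha criterion (isolated outliers)
#' are not covered by the shape; \code{\link{fire_hull}} handles those with
#' its small-count fallbacks.
#'
#' @param pts 2-column coordinate matrix (metres); at least 4 distinct,
#'   non-collinear points.
#' @param alpha Disk radius in metres.
#' @return An \code{fgeom}.
#' @export
alpha_shape <- function(pts, alpha) {
  pts <- coerce_pts(pts)
  upts <- unique(pts)
  if (nrow(upts) < 4)
    stop("alpha_shape: need at least 4 distinct points (use fallbacks)")
  if (collinear_pts(upts))
    stop("alpha_shape: degenerate (collinear) configuration")
  tri <- delaunay_triangulate(upts)
  cc <- circumcircle(upts, tri)
  keep <- cc$r2 <= alpha^2 * (1 + 1e-12)
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0)
    stop("alpha_shape: alpha too small, no triangles retained")
  rings <- tri_union_boundary(upts, tri)
  g <- fgeom(rings)
  attr(g, "triangles") <- tri
  attr(g, "points") <- upts
  attr(g, "covered") <- sort(unique(as.vector(tri)))
  g
}

# Sum of kept-triangle areas: exact area of the alpha shape (triangles in a
# triangulation are interior-disjoint).
alpha_area <- function(g) {
  tri <- attr(g, "triangles"); pts <- attr(g, "points")
  a <- pts[tri[, 1], , drop = FALSE]
  b <- pts[tri[, 2], , drop = FALSE]
  c3 <- pts[tri[, 3], , drop = FALSE]
  sum(abs((b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) -
          (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1])) / 2)
}
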