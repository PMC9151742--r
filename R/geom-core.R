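# Core planar vector-geometry primitives.
#
# Area geometries are stored as `fgeom`: a list of rings, each an open
# 2-column coordinate matrix (the closing edge is implicit). Rings follow
# the signed-orientation convention: counter-clockwise rings bound positive
# (filled) regions, clockwise rings bound holes, so that the total area is
# the sum of signed shoelace areas and point membership is even-odd. All
# coordinates are metres on the equal-area projected plane.

#' Planar area geometry
#'
#' Constructs an \code{fgeom}, the package's polygon/multipolygon container:
#' a list of rings (open 2-column matrices, metres) with counter-clockwise
#' outer rings and clockwise holes (even-odd semantics).
#'
#' @param rings List of 2-column numeric matrices, each with >= 3 rows.
#' @return An object of class \code{fgeom}.
#' @export
fgeom <- function(rings = list()) {
  rings <- Filter(function(m) is.matrix(m) && nrow(m) >= 3, rings)
  rings <- lapply(rings, function(m) {
    storage.mode(m) <- "double"
    dimnames(m) <- list(NULL, c("x", "y"))
    m
  })
  structure(list(rings = rings), class = "fgeom")
}

#' @export
print.fgeom <- function(x, ...) {
  cat(sprintf("<fgeom> %d ring(s), area %.6g m2\n",
              length(x$rings), fg_area(x)))
  invisible(x)
}

ring_area <- function(m) {
  n <- nrow(m)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2]) / 2
}

ring_length <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1)
  sum(sqrt((m[j, 1] - m[, 1])^2 + (m[j, 2] - m[, 2])^2))
}

ring_centroid <- function(m) {
  n <- nrow(m); j <- c(2:n, 1)
  cr <- m[, 1] * m[j, 2] - m[j, 1] * m[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(m))
  c(sum((m[, 1] + m[j, 1]) * cr) / (6 * a),
    sum((m[, 2] + m[j, 2]) * cr) / (6 * a))
}

#' Area, perimeter, centroid and bounding box of an fgeom
#'
#' \code{fg_area} sums signed ring areas (holes subtract); units m2.
#' \code{fg_perimeter} sums all ring lengths (hole boundaries included);
#' units m. \code{fg_centroid} is the area-weighted polygon centroid.
#'
#' @param g An \code{fgeom}.
#' @return Scalars (area m2, perimeter m), length-2 centroid, or a bbox
#'   vector \code{c(xmin, ymin, xmax, ymax)}.
#' @export
fg_area <- function(g) {
  if (fg_is_empty(g)) return(0)
  sum(vapply(g$rings, ring_area, 0))
}

#' @rdname fg_area
#' @export
fg_perimeter <- function(g) {
  if (fg_is_empty(g)) return(0)
  sum(vapply(g$rings, ring_length, 0))
}

#' @rdname fg_area
#' @export
fg_centroid <- function(g) {
  a <- vapply(g$rings, ring_area, 0)
  cs <- t(vapply(g$rings, ring_centroid, c(0, 0)))
  w <- a / sum(a)
  c(sum(cs[, 1] * w), sum(cs[, 2] * w))
}

#' @rdname fg_area
#' @export
fg_bbox <- function(g) {
  xs <- unlist(lapply(g$rings, function(m) m[, 1]))
  ys <- unlist(lapply(g$rings, function(m) m[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' @rdname fg_area
#' @export
fg_is_empty <- function(g) length(g$rings) == 0

# Even-odd crossing test of points against one ring (boundary not handled
# specially; callers needing boundary inclusion use fg_covers).
pts_in_ring <- function(pts, m) {
  n <- nrow(m); j <- c(2:n, 1)
  x1 <- m[, 1]; y1 <- m[, 2]; x2 <- m[j, 1]; y2 <- m[j, 2]
  inside <- logical(nrow(pts))
  for (k in seq_len(n)) {
    px <- pts[, 1]; py <- pts[, 2]
    crosses <- ((y1[k] > py) != (y2[k] > py))
    if (any(crosses)) {
      xint <- x1[k] + (py - y1[k]) * (x2[k] - x1[k]) / (y2[k] - y1[k])
      inside <- xor(inside, crosses & (px < xint))
    }
  }
  inside
}

#' Point membership and coverage
#'
#' \code{fg_contains} is the strict even-odd interior test; \code{fg_covers}
#' additionally accepts points within \code{tol} metres of the boundary, so
#' "on the perimeter" counts as covered.
#'
#' @param g An \code{fgeom}.
#' @param pts 2-column coordinate matrix.
#' @param tol Boundary tolerance in metres.
#' @return Logical vector.
#' @export
fg_contains <- function(g, pts) {
  pts <- coerce_pts(pts)
  if (fg_is_empty(g) || nrow(pts) == 0) return(logical(nrow(pts)))
  inside <- logical(nrow(pts))
  for (m in g$rings) inside <- xor(inside, pts_in_ring(pts, m))
  inside
}

#' @rdname fg_contains
#' @export
fg_covers <- function(g, pts, tol = 1e-6) {
  pts <- coerce_pts(pts)
  fg_contains(g, pts) | fg_boundary_dist(g, pts) <= tol
}

coerce_pts <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2, byrow = FALSE)
  if (!is.matrix(pts)) pts <- as.matrix(pts)
  pts
}

# All boundary segments of an fgeom as a matrix with columns
# x1, y1, x2, y2, ring, seg.
fg_segments <- function(g) {
  out <- lapply(seq_along(g$rings), function(i) {
    m <- g$rings[[i]]; n <- nrow(m); j <- c(2:n, 1)
    cbind(x1 = m[, 1], y1 = m[, 2], x2 = m[j, 1], y2 = m[j, 2],
          ring = i, seg = seq_len(n))
  })
  do.call(rbind, out)
}

# Minimum distance from each point to a set of segments (vectorised over
# segments, looped over points; sizes here are modest).
pts_segs_mindist <- function(pts, segs) {
  ax <- segs[, 1]; ay <- segs[, 2]
  dx <- segs[, 3] - ax; dy <- segs[, 4] - ay
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1]; py <- pts[i, 2]
    t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    min(sqrt((ax + t * dx - px)^2 + (ay + t * dy - py)^2))
  }, 0)
}

#' Distances to an fgeom
#'
#' \code{fg_boundary_dist} is the distance from each point to the geometry
#' boundary; \code{fg_dist} the distance from each point to the filled
#' region (zero for interior points); \code{fg_geom_dist} the shortest
#' distance between two geometries (zero if they overlap or touch).
#'
#' @param g,g1,g2 \code{fgeom} objects.
#' @param pts 2-column coordinate matrix.
#' @return Numeric vector (or scalar for \code{fg_geom_dist}), metres.
#' @export
fg_boundary_dist <- function(g, pts) {
  pts <- coerce_pts(pts)
  if (fg_is_empty(g)) return(rep(Inf, nrow(pts)))
  pts_segs_mindist(pts, fg_segments(g))
}

#' @rdname fg_boundary_dist
#' @export
fg_dist <- function(g, pts) {
  pts <- coerce_pts(pts)
  d <- fg_boundary_dist(g, pts)
  d[fg_contains(g, pts)] <- 0
  d
}

#' @rdname fg_boundary_dist
#' @export
fg_geom_dist <- function(g1, g2) {
  if (fg_is_empty(g1) || fg_is_empty(g2)) return(Inf)
  v1 <- do.call(rbind, g1$rings)
  v2 <- do.call(rbind, g2$rings)
  if (any(fg_contains(g2, v1)) || any(fg_contains(g1, v2))) return(0)
  min(min(fg_dist(g2, v1)), min(fg_dist(g1, v2)))
}

# Remove consecutive duplicate and collinear vertices from a ring.
ring_clean <- function(m, tol = 1e-9) {
  n <- nrow(m)
  if (n < 3) return(m)
  keep <- !duplicated(round(m / tol) * tol)
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  if (n < 3) return(m)
  # drop collinear vertices
  ip <- c(n, 1:(n - 1)); inx <- c(2:n, 1)
  v1 <- m - m[ip, , drop = FALSE]
  v2 <- m[inx, , drop = FALSE] - m
  cr <- abs(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  sc <- sqrt((v1[, 1]^2 + v1[, 2]^2) * (v2[, 1]^2 + v2[, 2]^2))
  keep <- cr > 1e-12 * pmax(sc, 1)
  if (sum(keep) >= 3) m <- m[keep, , drop = FALSE]
  m
}

# Assign even-odd orientation signs to rings read from external sources:
# rings nested at even depth become CCW (positive), odd depth CW (holes).
orient_fgeom <- function(g) {
  k <- length(g$rings)
  if (k <= 1) {
    if (k == 1 && ring_area(g$rings[[1]]) < 0)
      g$rings[[1]] <- g$rings[[1]][rev(seq_len(nrow(g$rings[[1]]))), ,
                                   drop = FALSE]
    return(g)
  }
  for (i in seq_len(k)) {
    p <- matrix(g$rings[[i]][1, ], ncol = 2)
    depth <- 0
    for (j in seq_len(k)) {
      if (j != i && pts_in_ring(p, g$rings[[j]])) depth <- depth + 1
    }
    want_ccw <- depth %% 2 == 0
    if ((ring_area(g$rings[[i]]) > 0) != want_ccw)
      g$rings[[i]] <- g$rings[[i]][rev(seq_len(nrow(g$rings[[i]]))), ,
                                   drop = FALSE]
  }
  g
}
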