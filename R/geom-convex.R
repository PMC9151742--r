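# Convex-polygon helpers: orientation, half-plane clipping
# (Sutherland-Hodgman), convex set difference, and small constructions
# (discs, capsules, Minkowski sums) used by the perimeter buffering and the
# area-clipping machinery.

# Ensure counter-clockwise orientation of a convex (or simple) ring.
ccw_ring <- function(m) {
  if (ring_area(m) < 0) m[rev(seq_len(nrow(m))), , drop = FALSE] else m
}

# Signed distance of points to the half-plane left of directed edge a->b
# (positive = left/inside for a CCW polygon edge).
edge_side <- function(pts, a, b) {
  (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
}

# Clip an arbitrary simple ring against the half-plane left of a->b
# (vectorised: each input vertex emits up to two output vertices, the
# vertex itself if kept and the edge-crossing point if the edge crosses).
clip_halfplane <- function(m, a, b) {
  n <- nrow(m)
  if (n < 3) return(m[0, , drop = FALSE])
  d <- edge_side(m, a, b)
  j <- c(2:n, 1)
  keep_v <- d >= 0
  cross <- (d > 0 & d[j] < 0) | (d < 0 & d[j] > 0)
  t <- ifelse(cross, d / (d - d[j]), 0)
  ix <- m[, 1] + t * (m[j, 1] - m[, 1])
  iy <- m[, 2] + t * (m[j, 2] - m[, 2])
  # slots: vertex i at 2i-1, crossing on edge i at 2i
  sel <- c(rbind(keep_v, cross))
  xs <- c(rbind(m[, 1], ix))[sel]
  ys <- c(rbind(m[, 2], iy))[sel]
  cbind(xs, ys, deparse.level = 0)
}

# Sutherland-Hodgman: clip subject ring (any simple ring, any orientation)
# by a convex CCW clip ring. The output may contain degenerate edges but
# its signed shoelace area is exact, which is all the area machinery needs.
sh_clip <- function(subject, clip_ccw) {
  m <- subject
  n <- nrow(clip_ccw)
  nx <- c(2:n, 1)
  applied <- 0L
  for (i in seq_len(n)) {
    if (nrow(m) == 0) break
    a <- clip_ccw[i, ]; b <- clip_ccw[nx[i], ]
    if (sum((b - a)^2) < 1e-12) next  # (near-)degenerate edge: no half-plane
    m <- clip_halfplane(m, a, b)
    applied <- applied + 1L
  }
  # a clip ring whose edges are all degenerate has no interior
  if (applied < 3L) return(m[0, , drop = FALSE])
  m
}

# Area of the intersection of an arbitrary simple ring with a convex CCW
# polygon, signed by the subject ring's orientation.
sh_clip_area <- function(subject, clip_ccw) {
  m <- sh_clip(subject, clip_ccw)
  if (nrow(m) < 3) 0 else ring_area(m)
}

# Convex difference P \ Q decomposed into disjoint convex pieces:
# P \ Q = union over edges i of Q of
#   P  intersect  (left of e_1) ... (left of e_{i-1})  intersect (right of e_i).
# Both P and Q must be convex CCW. Returns a list of CCW matrices.
convex_subtract <- function(P, Q) {
  Q <- ring_clean(Q)
  if (nrow(Q) < 3) return(list(ccw_ring(P)))
  out <- list()
  remain <- P
  n <- nrow(Q); nx <- c(2:n, 1)
  for (i in seq_len(n)) {
    if (nrow(remain) < 3) break
    a <- Q[i, ]; b <- Q[nx[i], ]
    if (sum((b - a)^2) < 1e-18) next  # degenerate edge: no half-plane
    # piece outside edge i (right of a->b): clip remain by half-plane b->a
    piece <- clip_halfplane(remain, b, a)
    # shoelace noise on metre-scale coordinates is ~1e-3 m2; smaller
    # pieces are numerically meaningless slivers
    if (nrow(piece) >= 3 && abs(ring_area(piece)) > 1e-3)
      out[[length(out) + 1]] <- ccw_ring(piece)
    remain <- clip_halfplane(remain, a, b)
  }
  out
}

# Are points strictly inside a convex CCW polygon (all edges at distance
# > tol on the left)?
pts_strictly_in_convex <- function(pts, P, tol = 1e-6) {
  n <- nrow(P); nx <- c(2:n, 1)
  ok <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    a <- P[i, ]; b <- P[nx[i], ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    ok <- ok & (edge_side(pts, a, b) / len > tol)
  }
  ok
}

# Global angular grid: arcs discretised on multiples of 2*pi/k so that
# coincident arcs from different pieces produce bitwise-identical vertices.
arc_points <- function(center, r, a0, a1, k) {
  while (a1 <= a0) a1 <- a1 + 2 * pi
  step <- 2 * pi / k
  i0 <- ceiling(a0 / step + 1e-9)
  i1 <- floor(a1 / step - 1e-9)
  ang <- c(a0, if (i1 >= i0) (i0:i1) * step, a1)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# Closed disc polygon on the global angular grid (CCW).
disc_polygon <- function(center, r, k) {
  ang <- 2 * pi * (0:(k - 1)) / k
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# Capsule: Minkowski sum of segment a-b with a disc of radius r (CCW).
capsule_polygon <- function(a, b, r, k) {
  th <- atan2(b[2] - a[2], b[1] - a[1])
  rbind(
    arc_points(b, r, th - pi / 2, th + pi / 2, k),
    arc_points(a, r, th + pi / 2, th + 3 * pi / 2, k)
  )
}

# Minkowski sum of a convex point set with a disc, via the convex hull of
# the translated disc vertices (exact for polygon (+) polygon).
minkowski_disc <- function(pts, r, k) {
  d <- disc_polygon(c(0, 0), r, k)
  allp <- cbind(rep(pts[, 1], each = nrow(d)) + d[, 1],
                rep(pts[, 2], each = nrow(d)) + d[, 2])
  h <- grDevices::chull(allp)
  ccw_ring(allp[h, , drop = FALSE])
}
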