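# Bowyer-Watson Delaunay triangulation.
#
# Pure-R incremental construction with vectorised in-circumcircle tests.
# Input sizes in this package are a few hundred to a few thousand points
# (fire pixels of one object), for which this is comfortably fast. Grid-
# aligned detections produce many exactly-cocircular quadruples, which are
# broken by a deterministic sub-micrometre perturbation applied only inside
# the triangulation; reported triangles always reference the original
# coordinates, so downstream areas are unaffected at the 375 m pixel scale.

circumcircle <- function(p, tri) {
  ax <- p[tri[, 1], 1]; ay <- p[tri[, 1], 2]
  bx <- p[tri[, 2], 1]; by <- p[tri[, 2], 2]
  cx <- p[tri[, 3], 1]; cy <- p[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[abs(d) < 1e-300] <- 1e-300
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  list(cx = ux, cy = uy, r2 = (ux - ax)^2 + (uy - ay)^2)
}

# Deterministic coordinate-independent jitter in (-0.5, 0.5), derived from
# the point index via a splitmix-style integer hash.
index_jitter <- function(n) {
  h <- (seq_len(n) * 2654435761) %% 2^31
  h <- (h * 40503) %% 2^31
  (h / 2^31) - 0.5
}

#' Delaunay triangulation of planar points
#'
#' @param pts 2-column coordinate matrix with >= 3 distinct, non-collinear
#'   points.
#' @return Integer matrix with 3 columns; each row indexes a CCW triangle
#'   of \code{pts}.
#' @export
delaunay_triangulate <- function(pts) {
  pts <- coerce_pts(pts)
  n0 <- nrow(pts)
  if (n0 < 3) stop("delaunay_triangulate: need at least 3 points")
  scale <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-9)
  work <- pts
  work[, 1] <- work[, 1] + index_jitter(n0) * scale * 1e-9
  work[, 2] <- work[, 2] + rev(index_jitter(n0)) * scale * 1e-9

  cx0 <- mean(range(work[, 1])); cy0 <- mean(range(work[, 2]))
  R <- 20 * scale
  super <- rbind(c(cx0 - 2 * R, cy0 - R), c(cx0 + 2 * R, cy0 - R),
                 c(cx0, cy0 + 2 * R))
  p <- rbind(work, super)
  si <- n0 + 1:3

  tri <- matrix(si, ncol = 3)
  cc <- circumcircle(p, tri)
  ccx <- cc$cx; ccy <- cc$cy; r2 <- cc$r2

  for (ip in seq_len(n0)) {
    px <- p[ip, 1]; py <- p[ip, 2]
    bad <- which((px - ccx)^2 + (py - ccy)^2 < r2 * (1 + 1e-12))
    if (length(bad) == 0) next  # should not happen inside super-triangle
    # cavity boundary: edges used exactly once among bad triangles
    bt <- tri[bad, , drop = FALSE]
    e <- rbind(bt[, c(1, 2)], bt[, c(2, 3)], bt[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
    keep <- setdiff(seq_len(nrow(tri)), bad)
    tri <- tri[keep, , drop = FALSE]
    ccx <- ccx[keep]; ccy <- ccy[keep]; r2 <- r2[keep]
    newtri <- cbind(once, ip)
    ncc <- circumcircle(p, newtri)
    tri <- rbind(tri, newtri)
    ccx <- c(ccx, ncc$cx); ccy <- c(ccy, ncc$cy); r2 <- c(r2, ncc$r2)
  }

  tri <- tri[rowSums(matrix(tri %in% si, ncol = 3)) == 0, , drop = FALSE]
  if (nrow(tri) == 0) stop("delaunay_triangulate: degenerate configuration")
  # orient CCW on the original coordinates
  a <- pts[tri[, 1], , drop = FALSE]
  b <- pts[tri[, 2], , drop = FALSE]
  cc3 <- pts[tri[, 3], , drop = FALSE]
  s <- (b[, 1] - a[, 1]) * (cc3[, 2] - a[, 2]) -
       (b[, 2] - a[, 2]) * (cc3[, 1] - a[, 1])
  flip <- s < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  tri[s != 0, , drop = FALSE]
}

collinear_pts <- function(pts, tol = 1e-9) {
  pts <- coerce_pts(pts)
  if (nrow(pts) < 3) return(TRUE)
  v <- sweep(pts, 2, colMeans(pts))
  sv <- svd(v)$d
  sv[2] <= tol * max(sv[1], 1)
}
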