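# Active fire front extraction.
#
# The active front is the part of the fire perimeter that is currently
# burning: the boundary segments that lie within a fixed radius (500 m by
# default) of the fire pixels newly detected at the current step. For each
# perimeter segment the sub-intervals within the radius of any new pixel
# are found exactly (each pixel contributes the solution interval of a
# quadratic in the segment parameter), and contiguous pieces are joined
# into linestrings. A front that wraps a whole ring is reported as a
# closed linear ring.

# Union of parameter intervals [0,1] where segment a-b is within r of any
# point in pts. Returns a 2-column matrix of disjoint intervals.
seg_near_intervals <- function(a, b, pts, r) {
  d <- b - a
  l2 <- sum(d^2)
  if (l2 < 1e-300) {
    near <- min((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2) <= r^2
    return(if (near) matrix(c(0, 1), 1) else matrix(0, 0, 2))
  }
  fx <- a[1] - pts[, 1]; fy <- a[2] - pts[, 2]
  bq <- (fx * d[1] + fy * d[2]) / l2
  cq <- (fx^2 + fy^2 - r^2) / l2
  disc <- bq^2 - cq
  ok <- disc >= 0
  if (!any(ok)) return(matrix(0, 0, 2))
  sq <- sqrt(disc[ok])
  lo <- pmax(0, -bq[ok] - sq)
  hi <- pmin(1, -bq[ok] + sq)
  iv <- cbind(lo, hi)[hi > lo, , drop = FALSE]
  if (nrow(iv) == 0) return(matrix(0, 0, 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      last <- nrow(merged)
      if (iv[k, 1] <= merged[last, 2] + 1e-12)
        merged[last, 2] <- max(merged[last, 2], iv[k, 2])
      else merged <- rbind(merged, iv[k, ])
    }
  }
  merged
}

#' Active fire front along a perimeter
#'
#' Extracts the subset of the hull boundary lying within \code{radius}
#' metres of any newly detected fire pixel.
#'
#' @param hull A \code{\link{fire_hull}} result (or an \code{fgeom}).
#' @param new_points 2-column matrix of projected new-pixel coordinates
#'   (metres); may have zero rows.
#' @param radius Search radius in metres (500 m by default).
#' @return A list of class \code{fed_fline}: \code{parts} (list of 2-column
#'   matrices, each an open polyline or, when \code{closed} is TRUE, a
#'   linear ring), \code{closed} (logical per part) and \code{length}
#'   (total length, metres).
#' @export
active_fireline <- function(hull, new_points, radius = 500) {
  g <- if (inherits(hull, "fed_hull")) hull$geom else hull
  new_points <- coerce_pts(new_points)
  parts <- list(); closed <- logical(0)
  if (!fg_is_empty(g) && nrow(new_points) > 0) {
    for (m in g$rings) {
      n <- nrow(m); nx <- c(2:n, 1)
      segs <- vector("list", n)
      full <- TRUE
      for (k in seq_len(n)) {
        iv <- seg_near_intervals(m[k, ], m[nx[k], ], new_points, radius)
        segs[[k]] <- iv
        if (!(nrow(iv) == 1 && iv[1, 1] <= 1e-12 && iv[1, 2] >= 1 - 1e-12))
          full <- FALSE
      }
      if (full) {
        parts[[length(parts) + 1]] <- m
        closed <- c(closed, TRUE)
        next
      }
      # chain consecutive covered pieces into polylines
      cur <- NULL
      ring_parts <- list()
      for (k in seq_len(n)) {
        a <- m[k, ]; b <- m[nx[k], ]
        iv <- segs[[k]]
        for (q in seq_len(nrow(iv))) {
          p0 <- a + iv[q, 1] * (b - a)
          p1 <- a + iv[q, 2] * (b - a)
          if (!is.null(cur) &&
              sqrt(sum((cur[nrow(cur), ] - p0)^2)) < 1e-9) {
            cur <- rbind(cur, p1)
          } else {
            if (!is.null(cur) && nrow(cur) >= 2)
              ring_parts[[length(ring_parts) + 1]] <- cur
            cur <- rbind(p0, p1)
          }
        }
      }
      if (!is.null(cur) && nrow(cur) >= 2) {
        # wrap-around: join last piece with first if contiguous
        if (length(ring_parts) > 0) {
          first <- ring_parts[[1]]
          if (sqrt(sum((cur[nrow(cur), ] - first[1, ])^2)) < 1e-9) {
            ring_parts[[1]] <- rbind(cur, first[-1, , drop = FALSE])
          } else ring_parts[[length(ring_parts) + 1]] <- cur
        } else ring_parts[[length(ring_parts) + 1]] <- cur
      }
      for (rp in ring_parts) {
        parts[[length(parts) + 1]] <- rp
        closed <- c(closed, FALSE)
      }
    }
  }
  parts <- lapply(parts, function(m) {
    dimnames(m) <- list(NULL, c("x", "y"))
    m
  })
  len <- 0
  for (i in seq_along(parts)) {
    m <- parts[[i]]
    if (closed[i]) len <- len + ring_length(m)
    else len <- len + sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2))
  }
  structure(list(parts = parts, closed = closed, length = len),
            class = "fed_fline")
}

#' @export
print.fed_fline <- function(x, ...) {
  cat(sprintf("<fed_fline> %d part(s), length %.3f km\n",
              length(x$parts), x$length / 1e3))
  invisible(x)
}
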