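# Outward buffering of the concave hull and the union-of-convex-pieces
# arrangement that powers it.
#
# The buffered perimeter is constructed as the union of convex pieces: the
# alpha-complex triangles themselves plus one capsule (segment Minkowski-
# summed with a disc) per boundary edge, which together realise a round-join
# outward buffer of the triangle union. The union boundary is extracted with
# a small arrangement: split every piece edge at its intersections with
# other pieces, drop fragments interior to the union, and stitch the
# survivors into rings. Arcs are discretised on a shared global angular
# grid so that coincident arcs from adjacent capsules produce identical
# vertices and can be deduplicated exactly.

# Intersection parameters between two edge sets. A1/A2 and B1/B2 are n x 2
# and m x 2 matrices of segment endpoints. Returns a list with vectors ti
# (parameter on A segs), tj (on B segs) and indices ei, ej, including
# projected endpoints of collinear overlaps.
edge_pair_ts <- function(A1, A2, B1, B2) {
  n <- nrow(A1); m <- nrow(B1)
  ei <- rep(seq_len(n), times = m)
  ej <- rep(seq_len(m), each = n)
  ax <- A1[ei, 1]; ay <- A1[ei, 2]
  dx1 <- A2[ei, 1] - ax; dy1 <- A2[ei, 2] - ay
  bx <- B1[ej, 1]; by <- B1[ej, 2]
  dx2 <- B2[ej, 1] - bx; dy2 <- B2[ej, 2] - by
  den <- dx1 * dy2 - dy1 * dx2
  rx <- bx - ax; ry <- by - ay
  out_ei <- integer(0); out_ej <- integer(0)
  out_ti <- numeric(0); out_tj <- numeric(0)
  nz <- abs(den) > 1e-12
  if (any(nz)) {
    t <- (rx[nz] * dy2[nz] - ry[nz] * dx2[nz]) / den[nz]
    u <- (rx[nz] * dy1[nz] - ry[nz] * dx1[nz]) / den[nz]
    ok <- t > -1e-9 & t < 1 + 1e-9 & u > -1e-9 & u < 1 + 1e-9
    out_ei <- ei[nz][ok]; out_ej <- ej[nz][ok]
    out_ti <- t[ok]; out_tj <- u[ok]
  }
  # collinear overlapping segments: register the other segment's endpoints
  par <- which(!nz & abs(rx * dy1 - ry * dx1) < 1e-9 * pmax(1, abs(dx1) + abs(dy1)))
  if (length(par)) {
    for (kk in par) {
      l2 <- dx1[kk]^2 + dy1[kk]^2
      if (l2 < 1e-300) next
      t0 <- ((bx[kk] - ax[kk]) * dx1[kk] + (by[kk] - ay[kk]) * dy1[kk]) / l2
      t1 <- t0 + (dx2[kk] * dx1[kk] + dy2[kk] * dy1[kk]) / l2
      for (tv in c(t0, t1)) {
        if (tv > 1e-9 && tv < 1 - 1e-9) {
          out_ei <- c(out_ei, ei[kk]); out_ej <- c(out_ej, ej[kk])
          out_ti <- c(out_ti, tv); out_tj <- c(out_tj, NA_real_)
        }
      }
    }
  }
  list(ei = out_ei, ej = out_ej, ti = out_ti, tj = out_tj)
}

bbox_of <- function(m) c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2]))

bbox_overlap <- function(b1, b2, tol = 1e-9) {
  !(b1[3] < b2[1] - tol || b2[3] < b1[1] - tol ||
    b1[4] < b2[2] - tol || b2[4] < b1[2] - tol)
}

#' Union of convex polygons with explicit boundary
#'
#' Computes the boundary rings of the union of a set of convex CCW
#' polygons, optionally united with an additional region given as a
#' point-membership predicate (used for the buffered-perimeter
#' construction, where the alpha polygon itself is that region and only
#' its edge capsules contribute boundary). Used internally to realise
#' buffered fire perimeters; exported because it is also handy for
#' assembling synthetic reference perimeters.
#'
#' @param pieces List of convex CCW 2-column matrices.
#' @param snap Vertex snapping tolerance in metres for ring stitching.
#' @param interior_test Optional function taking an n x 2 point matrix and
#'   returning a logical vector: TRUE for points strictly interior to an
#'   extra union member whose own boundary is already covered by
#'   \code{pieces}.
#' @return An \code{\link{fgeom}} whose CCW rings are outer boundaries and
#'   CW rings are holes.
#' @export
union_convex <- function(pieces, snap = 1e-6, interior_test = NULL) {
  pieces <- lapply(pieces, ccw_ring)
  np <- length(pieces)
  if (np == 0) return(fgeom())
  if (np == 1 && is.null(interior_test)) return(fgeom(pieces))
  bb <- t(vapply(pieces, bbox_of, numeric(4)))

  # drop pieces wholly contained in another piece
  alive <- rep(TRUE, np)
  areas <- vapply(pieces, ring_area, 0)
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (i == j || !alive[i]) next
      if (!bbox_overlap(bb[i, ], bb[j, ])) next
      if (areas[j] < areas[i] - 1e-9) next
      if (areas[j] < areas[i] + 1e-9 && j > i) next  # identical: keep first
      n <- nrow(pieces[[j]]); nx <- c(2:n, 1)
      inside <- TRUE
      for (k in seq_len(n)) {
        a <- pieces[[j]][k, ]; b <- pieces[[j]][nx[k], ]
        len <- sqrt(sum((b - a)^2)); if (len == 0) next
        if (any(edge_side(pieces[[i]], a, b) / len < -1e-7)) {
          inside <- FALSE; break
        }
      }
      if (inside && alive[j]) { alive[i] <- FALSE; break }
    }
  }
  pieces <- pieces[alive]; bb <- bb[alive, , drop = FALSE]
  np <- length(pieces)
  if (np == 1 && is.null(interior_test)) return(fgeom(pieces))

  # global edge table
  nv <- vapply(pieces, nrow, 0L)
  e_piece <- rep(seq_len(np), nv)
  E1 <- do.call(rbind, pieces)
  E2 <- do.call(rbind, lapply(pieces, function(m)
    m[c(2:nrow(m), 1), , drop = FALSE]))
  ne <- length(e_piece)
  ts <- vector("list", ne)
  edge_idx <- split(seq_len(ne), e_piece)

  for (i in seq_len(max(np - 1, 0))) {
    for (j in seq_len(np)) {
      if (j <= i) next
      if (!bbox_overlap(bb[i, ], bb[j, ])) next
      ii <- edge_idx[[i]]; jj <- edge_idx[[j]]
      res <- edge_pair_ts(E1[ii, , drop = FALSE], E2[ii, , drop = FALSE],
                          E1[jj, , drop = FALSE], E2[jj, , drop = FALSE])
      if (length(res$ei)) {
        for (k in seq_along(res$ei)) {
          gi <- ii[res$ei[k]]; gj <- jj[res$ej[k]]
          ts[[gi]] <- c(ts[[gi]], res$ti[k])
          if (!is.na(res$tj[k])) ts[[gj]] <- c(ts[[gj]], res$tj[k])
        }
      }
    }
  }

  # fragment edges
  fa <- vector("list", ne); fb <- vector("list", ne)
  for (ge in seq_len(ne)) {
    tv <- c(0, 1, pmin(1, pmax(0, ts[[ge]])))
    tv <- sort(unique(tv))
    tv <- tv[c(TRUE, diff(tv) > 1e-9)]
    a <- E1[ge, ]; b <- E2[ge, ]
    t0 <- tv[-length(tv)]; t1 <- tv[-1]
    fa[[ge]] <- cbind(a[1] + t0 * (b[1] - a[1]), a[2] + t0 * (b[2] - a[2]))
    fb[[ge]] <- cbind(a[1] + t1 * (b[1] - a[1]), a[2] + t1 * (b[2] - a[2]))
  }
  nfrag <- vapply(fa, nrow, 0L)
  frag_a <- do.call(rbind, fa)
  frag_b <- do.call(rbind, fb)
  frag_piece <- rep(e_piece, nfrag)
  nf <- nrow(frag_a)
  mid <- (frag_a + frag_b) / 2
  keep <- rep(TRUE, nf)
  for (i in seq_len(np)) {
    cand <- which(keep & frag_piece != i &
                  mid[, 1] >= bb[i, 1] - 1e-7 & mid[, 1] <= bb[i, 3] + 1e-7 &
                  mid[, 2] >= bb[i, 2] - 1e-7 & mid[, 2] <= bb[i, 4] + 1e-7)
    if (length(cand))
      keep[cand] <- !pts_strictly_in_convex(mid[cand, , drop = FALSE],
                                            pieces[[i]], tol = 1e-7)
  }
  if (!is.null(interior_test) && any(keep)) {
    kidx <- which(keep)
    keep[kidx] <- !interior_test(mid[kidx, , drop = FALSE])
  }
  frag_a <- frag_a[keep, , drop = FALSE]
  frag_b <- frag_b[keep, , drop = FALSE]

  # dedupe coincident fragments; opposite-direction pairs are interior
  ka <- paste(round(frag_a[, 1] / snap), round(frag_a[, 2] / snap))
  kb <- paste(round(frag_b[, 1] / snap), round(frag_b[, 2] / snap))
  fkey <- ifelse(ka < kb, paste(ka, kb), paste(kb, ka))
  dirn <- ka < kb
  keep2 <- rep(TRUE, length(fkey))
  for (grp in split(seq_along(fkey), fkey)) {
    if (length(grp) > 1) {
      if (length(unique(dirn[grp])) > 1) keep2[grp] <- FALSE  # interior pair
      else keep2[grp[-1]] <- FALSE                            # duplicate
    }
  }
  # degenerate zero-length fragments
  keep2 <- keep2 & (ka != kb)
  frag_a <- frag_a[keep2, , drop = FALSE]
  frag_b <- frag_b[keep2, , drop = FALSE]
  ka <- ka[keep2]; kb <- kb[keep2]
  nf <- nrow(frag_a)
  if (nf == 0) return(fgeom())

  # stitch fragments into rings
  bystart <- split(seq_len(nf), ka)
  used <- rep(FALSE, nf)
  rings <- list()
  repeat {
    s <- which(!used)[1]
    if (is.na(s)) break
    path <- list(frag_a[s, ])
    cur <- s
    repeat {
      used[cur] <- TRUE
      path[[length(path) + 1]] <- frag_b[cur, ]
      nxt <- bystart[[kb[cur]]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      if (length(nxt) > 1) {
        vin <- frag_a[cur, ] - frag_b[cur, ]
        a_in <- atan2(vin[2], vin[1])
        angs <- vapply(nxt, function(ci) {
          vout <- frag_b[ci, ] - frag_a[ci, ]
          (a_in - atan2(vout[2], vout[1])) %% (2 * pi)
        }, 0)
        nxt <- nxt[which.min(angs)]
      }
      cur <- nxt
    }
    m <- do.call(rbind, path)
    # drop closing duplicate vertex
    if (nrow(m) > 1 && sqrt(sum((m[1, ] - m[nrow(m), ])^2)) < 10 * snap)
      m <- m[-nrow(m), , drop = FALSE]
    m <- ring_clean(m, tol = snap)
    if (nrow(m) >= 3 && abs(ring_area(m)) > 1e-6)
      rings[[length(rings) + 1]] <- m
  }
  fgeom(rings)
}

#' Fire perimeter from pixel locations
#'
#' Builds the vector fire perimeter from projected fire-pixel locations.
#' With four or more non-collinear pixels the perimeter is the alpha-shape
#' concave hull expanded outward by \code{buffer} metres (half the 375 m
#' nadir pixel width by default); with exactly three pixels (or a collinear
#' arrangement, where the alpha complex is undefined) the convex hull is
#' buffered instead; with one or two pixels the perimeter is the union of
#' circles of radius \code{buffer} centred on the pixels. Pixels left
#' uncovered by the alpha complex (isolated outliers) receive their own
#' buffer circle so that every input pixel lies inside the perimeter.
#'
#' @param pts 2-column matrix of projected pixel coordinates (metres).
#' @param alpha Alpha-shape disk radius, metres.
#' @param buffer Outward buffer, metres.
#' @param arc_segments Global angular grid resolution for buffer arcs.
#' @param circle_segments Angular resolution of the 1-2 pixel circle
#'   fallback and of isolated-pixel circles.
#' @return A list of class \code{fed_hull} with elements \code{geom}
#'   (\code{fgeom}), \code{area} (m2), \code{perim} (m), \code{npix} and
#'   \code{method} ("alpha", "convex" or "circle").
#' @export
fire_hull <- function(pts, alpha = 1000, buffer = 187.5,
                      arc_segments = 16, circle_segments = 128) {
  pts <- coerce_pts(pts)
  if (nrow(pts) == 0) stop("fire_hull: empty point set")
  upts <- unique(pts)
  n <- nrow(upts)
  geom <- NULL; method <- NULL

  if (n >= 4 && !collinear_pts(upts)) {
    ash <- tryCatch(alpha_shape(upts, alpha), error = function(e) NULL)
    if (!is.null(ash)) {
      if (buffer <= 0) {
        geom <- ash
      } else {
        # boundary of the buffered union comes entirely from the edge
        # capsules (and isolated-pixel discs); the alpha polygon itself
        # enters as an interior-membership test, since every point of its
        # own boundary is covered by a capsule
        pieces <- list()
        for (rg in ash$rings) {
          nr <- nrow(rg); nx <- c(2:nr, 1)
          for (k in seq_len(nr))
            pieces[[length(pieces) + 1]] <-
              capsule_polygon(rg[k, ], rg[nx[k], ], buffer, arc_segments)
        }
        covered <- attr(ash, "covered")
        for (iu in setdiff(seq_len(n), covered))
          pieces[[length(pieces) + 1]] <-
            disc_polygon(upts[iu, ], buffer, circle_segments)
        inside_alpha <- function(pts)
          fg_contains(ash, pts) & fg_boundary_dist(ash, pts) > 1e-7
        geom <- union_convex(pieces, interior_test = inside_alpha)
      }
      method <- "alpha"
    }
  }
  if (is.null(geom) && n >= 3) {
    h <- grDevices::chull(upts)
    geom <- fgeom(list(minkowski_disc(upts[h, , drop = FALSE], buffer,
                                      circle_segments)))
    method <- "convex"
  }
  if (is.null(geom)) {
    pieces <- lapply(seq_len(n), function(i)
      disc_polygon(upts[i, ], buffer, circle_segments))
    geom <- union_convex(pieces)
    method <- "circle"
  }
  structure(list(geom = geom, area = fg_area(geom),
                 perim = fg_perimeter(geom), npix = nrow(pts),
                 method = method),
            class = "fed_hull")
}

#' @export
print.fed_hull <- function(x, ...) {
  cat(sprintf("<fed_hull> %s, %d pixel(s), area %.4f km2, perimeter %.3f km\n",
              x$method, x$npix, x$area / 1e6, x$perim / 1e3))
  invisible(x)
}
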