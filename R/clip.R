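# Polygon area machinery: ear-clipping triangulation and exact areas of
# intersections and unions of fgeom geometries.
#
# Areas of boolean combinations are computed without constructing explicit
# boolean geometry: one operand is decomposed into signed triangles (sign
# +1 for outer rings, -1 for holes; holes nest inside outers under the
# even-odd convention, so inclusion-exclusion over ring pairs is exact)
# and each triangle is clipped against the other operand's rings with
# Sutherland-Hodgman half-plane clipping, whose enclosed signed area is
# exact even when the output carries degenerate edges.

# Ear-clipping triangulation of a simple ring (any orientation).
# Returns a list of CCW 3x2 matrices.
earclip_ring <- function(m) {
  m <- ring_clean(m)
  if (ring_area(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  n <- nrow(m)
  if (n < 3) return(list())
  if (n == 3) return(list(m))
  idx <- seq_len(n)
  out <- list()
  guard <- 0
  while (length(idx) > 3 && guard < 10 * n) {
    guard <- guard + 1
    k <- length(idx)
    found <- FALSE
    for (q in seq_len(k)) {
      ip <- idx[if (q == 1) k else q - 1]
      ic <- idx[q]
      inx <- idx[if (q == k) 1 else q + 1]
      a <- m[ip, ]; b <- m[ic, ]; c3 <- m[inx, ]
      cr <- (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1])
      if (cr <= 1e-12) next  # reflex or degenerate corner
      tri <- rbind(a, b, c3)
      others <- setdiff(idx, c(ip, ic, inx))
      if (length(others) &&
          any(pts_strictly_in_convex(m[others, , drop = FALSE], tri,
                                     tol = -1e-9)))
        next
      out[[length(out) + 1]] <- tri
      idx <- idx[-q]
      found <- TRUE
      break
    }
    if (!found) {
      # numerically stuck: shave the most convex corner
      k <- length(idx)
      best <- 1; bestcr <- -Inf
      for (q in seq_len(k)) {
        ip <- idx[if (q == 1) k else q - 1]
        ic <- idx[q]
        inx <- idx[if (q == k) 1 else q + 1]
        a <- m[ip, ]; b <- m[ic, ]; c3 <- m[inx, ]
        cr <- (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1])
        if (cr > bestcr) { bestcr <- cr; best <- q }
      }
      q <- best
      ip <- idx[if (q == 1) length(idx) else q - 1]
      ic <- idx[q]
      inx <- idx[if (q == length(idx)) 1 else q + 1]
      tri <- rbind(m[ip, ], m[ic, ], m[inx, ])
      if (ring_area(tri) > 1e-9) out[[length(out) + 1]] <- tri
      idx <- idx[-q]
    }
  }
  if (length(idx) == 3) {
    tri <- m[idx, , drop = FALSE]
    if (ring_area(tri) > 1e-12) out[[length(out) + 1]] <- tri
    else if (ring_area(tri) < -1e-12)
      out[[length(out) + 1]] <- tri[3:1, , drop = FALSE]
  }
  out
}

# Signed triangles of an fgeom: list of (tri, sign) with sign +1 for CCW
# (outer) rings and -1 for CW (hole) rings.
geom_signed_triangles <- function(g) {
  out <- list()
  for (m in g$rings) {
    s <- if (ring_area(m) >= 0) 1 else -1
    for (tri in earclip_ring(m))
      out[[length(out) + 1]] <- list(tri = tri, sign = s)
  }
  out
}

#' Exact areas of polygon overlays
#'
#' \code{fg_intersection_area} returns the area of the intersection of two
#' geometries; \code{fg_union_area} the area of the union of a list of
#' (possibly overlapping) geometries. Both handle holes via the signed-ring
#' convention. Units: m2.
#'
#' @param a,b \code{fgeom} objects.
#' @param geoms List of \code{fgeom} objects.
#' @return Area in m2.
#' @export
fg_intersection_area <- function(a, b) {
  if (fg_is_empty(a) || fg_is_empty(b)) return(0)
  ba <- fg_bbox(a); bb <- fg_bbox(b)
  if (!bbox_overlap(ba, bb)) return(0)
  tris <- geom_signed_triangles(b)
  total <- 0
  for (tb in tris) {
    tb_bb <- bbox_of(tb$tri)
    for (m in a$rings) {
      if (!bbox_overlap(bbox_of(m), tb_bb)) next
      total <- total + tb$sign * sh_clip_area(m, tb$tri)
    }
  }
  total
}

#' @rdname fg_intersection_area
#' @export
fg_union_area <- function(geoms) {
  geoms <- Filter(function(g) !fg_is_empty(g), geoms)
  if (length(geoms) == 0) return(0)
  if (length(geoms) == 1) return(fg_area(geoms[[1]]))
  if (length(geoms) == 2)
    return(fg_area(geoms[[1]]) + fg_area(geoms[[2]]) -
           fg_intersection_area(geoms[[1]], geoms[[2]]))
  if (geoms_pairwise_disjoint(geoms))
    return(sum(vapply(geoms, fg_area, 0)))
  pieces <- disjoint_pieces(geoms)
  sum(vapply(pieces, ring_area, 0))
}

# Quick mutual-disjointness check for a list of geometries (bbox prefilter
# then boundary distance).
geoms_pairwise_disjoint <- function(geoms, tol = 1e-9) {
  n <- length(geoms)
  if (n <= 1) return(TRUE)
  bbs <- lapply(geoms, fg_bbox)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!bbox_overlap(bbs[[i]], bbs[[j]])) next
      if (fg_geom_dist(geoms[[i]], geoms[[j]]) <= tol) return(FALSE)
    }
  }
  TRUE
}

# Decompose a list of geometries into disjoint convex CCW pieces covering
# their union: each geometry's positive triangles minus its hole triangles,
# then later geometries minus everything already accumulated. Geometries
# are processed largest-first so that nested or mostly-covered members
# (e.g. the cumulative footprints of one growing fire) are subtracted away
# cheaply instead of fragmenting the accumulator.
disjoint_pieces <- function(geoms) {
  if (length(geoms) > 1)
    geoms <- geoms[order(vapply(geoms, fg_area, 0), decreasing = TRUE)]
  acc <- list()
  acc_bb <- NULL
  for (g in geoms) {
    gp <- list()
    for (m in g$rings) {
      if (ring_area(m) >= 0) for (tri in earclip_ring(m)) gp[[length(gp) + 1]] <- tri
    }
    for (m in g$rings) {
      if (ring_area(m) < 0) {
        for (htri in earclip_ring(m)) {
          hb <- bbox_of(htri)
          newgp <- list()
          for (p in gp) {
            if (!bbox_overlap(bbox_of(p), hb)) { newgp[[length(newgp) + 1]] <- p; next }
            for (q in convex_subtract(p, htri)) newgp[[length(newgp) + 1]] <- q
          }
          gp <- newgp
        }
      }
    }
    # subtract the accumulated union from this geometry's pieces
    for (p in gp) {
      frags <- list(p)
      pb <- bbox_of(p)
      for (ai in seq_along(acc)) {
        if (!bbox_overlap(acc_bb[[ai]], pb)) next
        newfrags <- list()
        for (f in frags) {
          if (!bbox_overlap(bbox_of(f), acc_bb[[ai]])) {
            newfrags[[length(newfrags) + 1]] <- f; next
          }
          for (q in convex_subtract(f, acc[[ai]]))
            newfrags[[length(newfrags) + 1]] <- q
        }
        frags <- newfrags
        if (length(frags) == 0) break
      }
      for (f in frags) {
        acc[[length(acc) + 1]] <- f
        acc_bb[[length(acc_bb) + 1]] <- bbox_of(f)
      }
    }
  }
  acc
}

# Intersection area between the union of a list of geometries and a single
# geometry (used for per-fire scores on merged prediction sets). When the
# list members are mutually disjoint -- the common case for tracked fire
# hulls -- the reference is decomposed into convex pieces and each member's
# rings are clipped against them, avoiding triangulation of the (large)
# hull rings. Otherwise the members are disjointified first.
union_intersection_area <- function(geoms, ref) {
  geoms <- Filter(function(g) !fg_is_empty(g), geoms)
  if (length(geoms) == 0 || fg_is_empty(ref)) return(0)
  if (geoms_pairwise_disjoint(geoms))
    return(sum(vapply(geoms, fg_intersection_area, 0, b = ref)))
  pieces <- disjoint_pieces(geoms)
  rb <- fg_bbox(ref)
  total <- 0
  for (p in pieces) {
    if (!bbox_overlap(bbox_of(p), rb)) next
    for (m in ref$rings) {
      if (!bbox_overlap(bbox_of(m), bbox_of(p))) next
      total <- total + sh_clip_area(m, p)
    }
  }
  total
}
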