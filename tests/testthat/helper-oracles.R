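# Independent brute-force oracles and small fixture builders used across
# the test files.

# O(n^4) alpha-shape area: enumerate all point triples, keep a triangle if
# its circumcircle contains no other point (Delaunay) and its circumradius
# is at most alpha; triangles of a triangulation are interior-disjoint so
# the union area is the sum of triangle areas.
brute_alpha_area <- function(pts, alpha) {
  n <- nrow(pts)
  total <- 0
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        a <- pts[i, ]; b <- pts[j, ]; c3 <- pts[k, ]
        d <- 2 * (a[1] * (b[2] - c3[2]) + b[1] * (c3[2] - a[2]) +
                  c3[1] * (a[2] - b[2]))
        if (abs(d) < 1e-12) next
        a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c3^2)
        ux <- (a2 * (b[2] - c3[2]) + b2 * (c3[2] - a[2]) +
               c2 * (a[2] - b[2])) / d
        uy <- (a2 * (c3[1] - b[1]) + b2 * (a[1] - c3[1]) +
               c2 * (b[1] - a[1])) / d
        r2 <- (ux - a[1])^2 + (uy - a[2])^2
        if (r2 > alpha^2 * (1 + 1e-12)) next
        others <- setdiff(seq_len(n), c(i, j, k))
        if (length(others)) {
          d2 <- (pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2
          if (any(d2 < r2 * (1 - 1e-12))) next
        }
        total <- total + abs((b[1] - a[1]) * (c3[2] - a[2]) -
                             (b[2] - a[2]) * (c3[1] - a[1])) / 2
      }
    }
  }
  total
}

# Union-find single-linkage clustering oracle.
brute_clusters <- function(pts, linkage) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d <= linkage) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# Simple axis-aligned square as an fgeom (side s, lower-left at (x, y)).
square_geom <- function(x, y, s) {
  fgeom(list(rbind(c(x, y), c(x + s, y), c(x + s, y + s), c(x, y + s))))
}

# Minimal hand-built fire object for attribute tests.
make_fire <- function(id, pts, step, frp = NULL, config = fed_config()) {
  n <- nrow(pts)
  if (is.null(frp)) frp <- rep(1, n)
  ll <- fed_unproject(pts[, 1], pts[, 2], config$proj)
  px <- data.frame(x = pts[, 1], y = pts[, 2], lon = ll[, 1], lat = ll[, 2],
                   frp = frp, t = rep(unclass(step), n),
                   origin = rep(id, n), new = TRUE, ign = TRUE)
  f <- list(id = id, pixels = px, t_st = step, t_ed = step,
            invalid = FALSE, isactive = TRUE, t_inactive = 0,
            hull = NULL, fline = NULL, ftype = NA_character_,
            properties = list())
  f$hull <- fire_hull(pts, alpha = config$alpha,
                      buffer = config$pixel_buffer,
                      arc_segments = config$arc_segments,
                      circle_segments = config$circle_segments)
  f$fline <- active_fireline(f$hull, pts, config$fline_radius)
  f
}

# Default single-fire spread scenario used by several test files.
default_fire_run <- function(seed = 7, duration = 10, extra_steps = 2L,
                             config = fed_config()) {
  scn <- spread_scenario(seed = seed, duration = duration)
  truth <- simulate_spread(scn, config$proj)
  recs <- sample_detections(truth, config)
  res <- track_records(recs, start = scn$start,
                       end = step_succ(scn$start, duration - 1L + extra_steps),
                       config = config, keep_history = TRUE)
  list(scn = scn, truth = truth, recs = recs, res = res,
       state = res$state)
}
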