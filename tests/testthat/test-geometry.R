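# Projection, alpha-shape hulls, perimeter fallbacks and buffering.

test_that("projection round-trips and preserves geodesic distance", {
  pts <- cbind(lon = c(-121, -120.5, -118.2, -124),
               lat = c(38, 37.8, 34.1, 41.9))
  xy <- fed_project(pts[, 1], pts[, 2])
  back <- fed_unproject(xy[, 1], xy[, 2])
  expect_lt(max(abs(back - pts)), 1e-6)
  # identical inputs give identical outputs
  expect_identical(fed_project(-121, 38), fed_project(-121, 38))
  # two points 0.01 degrees apart in latitude are ~1.11 km apart
  a <- fed_project(-120, 38); b <- fed_project(-120, 38.01)
  d_plane <- sqrt(sum((a - b)^2))
  d_geo <- geosphere::distGeo(c(-120, 38), c(-120, 38.01))
  expect_lt(abs(d_plane - d_geo) / d_geo, 0.005)
  expect_equal(d_plane / 1000, 1.11, tolerance = 0.01)
})

test_that("alpha shape of a small square with large alpha is the square", {
  pts <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  g <- alpha_shape(pts, 1000)
  expect_equal(fg_area(g), 100 * 100, tolerance = 1e-12)
  expect_length(g$rings, 1)
})

test_that("two distant clumps give a two-part multipolygon", {
  set.seed(1)
  c1 <- cbind(runif(10, 0, 500), runif(10, 0, 500))
  c2 <- cbind(runif(10, 5000, 5500), runif(10, 0, 500))
  g <- alpha_shape(rbind(c1, c2), 1000)
  expect_length(g$rings, 2)
  expect_true(all(vapply(g$rings, firetrackr:::ring_area, 0) > 0))
})

test_that("very large alpha equals the convex hull", {
  set.seed(3)
  pts <- cbind(runif(20, 0, 1000), runif(20, 0, 1000))
  g <- alpha_shape(pts, 1e7)
  h <- grDevices::chull(pts)
  hull_area <- firetrackr:::ring_area(
    firetrackr:::ccw_ring(pts[h, , drop = FALSE]))
  expect_equal(fg_area(g), hull_area, tolerance = 1e-12)
})

test_that("alpha shape area matches the brute-force Delaunay oracle", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(6:25, 1)
    pts <- cbind(runif(n, 0, 4000), runif(n, 0, 4000))
    alpha <- runif(1, 600, 2500)
    want <- brute_alpha_area(pts, alpha)
    got <- tryCatch(fg_area(alpha_shape(pts, alpha)), error = function(e) 0)
    if (want == 0) expect_equal(got, 0)
    else expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("alpha-shape area is monotone in alpha", {
  set.seed(5)
  pts <- cbind(runif(40, 0, 5000), runif(40, 0, 5000))
  alphas <- c(700, 1000, 1500, 2500, 5000)
  areas <- vapply(alphas, function(a)
    tryCatch(fg_area(alpha_shape(pts, a)), error = function(e) 0), 0)
  expect_true(all(diff(areas) >= -1e-9))
})

test_that("single-pixel perimeter is a circle of the buffer radius", {
  h <- fire_hull(matrix(c(0, 0), 1), buffer = 187.5)
  expect_equal(h$method, "circle")
  expect_equal(h$area, pi * 187.5^2, tolerance = 1e-3)
  expect_equal(h$area / 1e6, 0.1104, tolerance = 1e-3)
})

test_that("two-pixel perimeter is the union of two circles", {
  h <- fire_hull(rbind(c(0, 0), c(250, 0)), buffer = 187.5)
  # overlapping circles: more than one disc, less than two
  expect_gt(h$area, pi * 187.5^2)
  expect_lt(h$area, 2 * pi * 187.5^2)
  expect_true(all(fg_covers(h$geom, rbind(c(0, 0), c(250, 0)))))
  # disjoint circles: two rings, twice the disc area
  h2 <- fire_hull(rbind(c(0, 0), c(5000, 0)), buffer = 187.5)
  expect_length(h2$geom$rings, 2)
  expect_equal(h2$area, 2 * pi * 187.5^2, tolerance = 1e-3)
})

test_that("three pixels fall back to a buffered convex hull", {
  pts <- rbind(c(0, 0), c(375, 0), c(190, 300))
  h <- fire_hull(pts)
  expect_equal(h$method, "convex")
  expect_true(all(fg_covers(h$geom, pts)))
  tri_area <- firetrackr:::ring_area(firetrackr:::ccw_ring(pts))
  expect_gt(h$area, tri_area)
})

test_that("collinear point sets fall back to the convex branch", {
  pts <- cbind(seq(0, 1500, by = 375), 0)
  h <- fire_hull(pts)
  expect_equal(h$method, "convex")
  expect_true(all(fg_covers(h$geom, pts)))
  expect_gt(h$area, 0)
})

test_that("gridded pixels give a single containing hull larger than the bare alpha shape", {
  gx <- seq(0, 13 * 375, by = 375)
  pts <- cbind(rep(gx, 14), rep(gx, each = 14))
  h <- fire_hull(pts, alpha = 1000, buffer = 187.5)
  expect_equal(h$method, "alpha")
  expect_length(h$geom$rings, 1)
  expect_true(all(fg_covers(h$geom, pts, tol = 1e-6)))
  bare <- fg_area(alpha_shape(pts, 1000))
  expect_gte(h$area, bare)
})

test_that("buffered hulls contain every input pixel on random point sets", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(4:120, 1)
    pts <- cbind(runif(n, 0, 6000), runif(n, 0, 6000))
    h <- fire_hull(pts)
    expect_true(all(fg_covers(h$geom, pts, tol = 1e-6)))
    expect_gt(h$area, 0)
    expect_equal(fg_area(h$geom), h$area)
  }
})
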