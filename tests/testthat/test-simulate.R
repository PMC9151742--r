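# The synthetic fire-spread and static-hotspot detection simulator.

test_that("elliptical growth has the analytic area and is nested", {
  cfg <- fed_config()
  scn <- spread_scenario(rate_along = 500, rate_cross = 250, duration = 4,
                         seed = 1)
  truth <- simulate_spread(scn, cfg$proj)
  a4 <- fg_area(truth$footprints[[4]])
  expect_equal(a4 / 1e6, pi * 2 * 1, tolerance = 2e-3)   # 6.283 km2
  # nesting: each footprint contains the previous boundary vertices
  for (k in 2:4) {
    prev <- do.call(rbind, truth$footprints[[k - 1]]$rings)
    expect_true(all(fg_covers(truth$footprints[[k]], prev, tol = 1e-6)))
  }
})

test_that("zero growth keeps the ignition disc footprint", {
  cfg <- fed_config()
  scn <- spread_scenario(rate_along = 0, rate_cross = 0, duration = 3,
                         seed = 1)
  truth <- simulate_spread(scn, cfg$proj)
  a <- vapply(truth$footprints, fg_area, 0)
  expect_equal(a[1], a[3], tolerance = 1e-12)
  expect_equal(a[1] / 1e6, pi * (375 / 2)^2 / 1e6, tolerance = 5e-3)
})

test_that("the same seed reproduces the detection stream exactly", {
  cfg <- fed_config()
  scn <- spread_scenario(seed = 42, duration = 5)
  r1 <- sample_detections(simulate_spread(scn, cfg$proj), cfg)
  r2 <- sample_detections(simulate_spread(scn, cfg$proj), cfg)
  expect_identical(r1, r2)
  s1 <- simulate_static_source(c(-120, 37), fed_step("20200801AM"), 10,
                               seed = 9, config = cfg)
  s2 <- simulate_static_source(c(-120, 37), fed_step("20200801AM"), 10,
                               seed = 9, config = cfg)
  expect_identical(s1, s2)
})

test_that("perfect detection with no jitter returns every lattice node", {
  cfg <- fed_config()
  scn <- spread_scenario(rate_along = 600, rate_cross = 400, duration = 3,
                         detect_prob = 1, jitter_sd = 0, seed = 2)
  truth <- simulate_spread(scn, cfg$proj)
  recs <- sample_detections(truth, cfg)
  # independent node count: lattice points inside the analytic ellipse
  ign <- fed_project(scn$ignition[, 1], scn$ignition[, 2], cfg$proj)
  th <- scn$wind_deg * pi / 180
  nodes_in <- function(k) {
    a <- k * scn$rate_along; b <- k * scn$rate_cross
    gx <- seq(floor((ign[1] - a - 375) / 375), ceiling((ign[1] + a + 375) / 375)) * 375
    gy <- seq(floor((ign[2] - a - 375) / 375), ceiling((ign[2] + a + 375) / 375)) * 375
    g <- expand.grid(x = gx, y = gy)
    dx <- g$x - ign[1]; dy <- g$y - ign[2]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    sum((u / a)^2 + (v / b)^2 <= 1)
  }
  expect_equal(nrow(recs), nodes_in(3))
  # all detection positions are lattice nodes (no jitter)
  xy <- fed_project(recs$lon, recs$lat, cfg$proj)
  expect_lt(max(abs(xy / 375 - round(xy / 375))), 1e-6)
})

test_that("detection counts respect the binomial detection probability", {
  cfg <- fed_config()
  full <- spread_scenario(rate_along = 600, rate_cross = 400, duration = 4,
                          detect_prob = 1, jitter_sd = 0, seed = 3)
  nfull <- nrow(sample_detections(simulate_spread(full, cfg$proj), cfg))
  half <- spread_scenario(rate_along = 600, rate_cross = 400, duration = 4,
                          detect_prob = 0.5, jitter_sd = 0, seed = 3)
  nhalf <- nrow(sample_detections(simulate_spread(half, cfg$proj), cfg))
  bounds <- qbinom(c(0.005, 0.995), nfull, 0.5)
  expect_gte(nhalf, bounds[1])
  expect_lte(nhalf, bounds[2])
})

test_that("static sources emit 1-3 tight detections per step", {
  cfg <- fed_config()
  recs <- simulate_static_source(c(-120.1, 37.5), fed_step("20200801AM"),
                                 30, seed = 4, config = cfg)
  expect_gte(nrow(recs), 30)
  expect_lte(nrow(recs), 90)
  xy <- fed_project(recs$lon, recs$lat, cfg$proj)
  spread <- max(dist(xy))
  expect_lt(spread, 1000)   # well under 1 km2 once hulled
  one <- simulate_static_source(c(-120.1, 37.5), fed_step("20200801AM"),
                                1, seed = 4, config = cfg)
  expect_gte(nrow(one), 1)
  expect_lte(nrow(one), 3)
})

test_that("synthetic rasters honour the class composition", {
  extent <- c(0, 0, 10000, 10000)
  r <- synth_rasters(extent, c(forest = 0.6, shrub = 0.4), fm_mean = 15)
  cls <- landcover_classes()
  frac_forest <- mean(r$lct$values == cls[["forest"]])
  expect_equal(frac_forest, 0.6, tolerance = 0.05)
  expect_equal(mean(r$fm1000$values), 15, tolerance = 0.5)
  uni <- synth_rasters(extent, c(forest = 1))
  expect_true(all(uni$lct$values == cls[["forest"]]))
  expect_error(synth_rasters(extent, c(forest = 0.6, shrub = 0.5)),
               "sum to 1")
})

test_that("detection CSV round-trips through the ingest dialect", {
  cfg <- fed_config()
  scn <- spread_scenario(seed = 6, duration = 3)
  recs <- sample_detections(simulate_spread(scn, cfg$proj), cfg)
  path <- tempfile(fileext = ".csv")
  write_detections_csv(recs, path, cfg)
  back <- read_detections(path, cfg)
  expect_equal(nrow(back), nrow(recs))
  expect_equal(back$lat, recs$lat, tolerance = 1e-9)
  expect_equal(back$acq_min, recs$acq_min)
  expect_equal(back$type, recs$type)
})
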