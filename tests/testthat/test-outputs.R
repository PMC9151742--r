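# State serialization, snapshots, large-fire series and season summary.

test_that("state save/load is an exact round trip", {
  run <- default_fire_run(seed = 5, duration = 6, extra_steps = 1L)
  st <- run$state
  path <- tempfile(fileext = ".json")
  save_state(st, path)
  st2 <- load_state(path)
  expect_true(isTRUE(all.equal(st, st2, tolerance = 0)))
})

test_that("corrupt or truncated state files fail to load", {
  run <- default_fire_run(seed = 5, duration = 4, extra_steps = 0L)
  path <- tempfile(fileext = ".json")
  save_state(run$state, path)
  txt <- readLines(path)
  writeLines(substr(txt, 1, nchar(txt) %/% 2), path)
  expect_error(load_state(path))
  writeLines("{\"format\": \"something_else\"}", path)
  expect_error(load_state(path), "not a tracker state")
})

test_that("snapshots include only valid fires and non-empty firelines", {
  cfg <- fed_config()
  step <- fed_step("20200801AM")
  state <- allfires_init(cfg)
  state$t <- step
  f1 <- make_fire(1L, rbind(c(0, 0), c(375, 0), c(0, 375), c(375, 375)),
                  step, config = cfg)
  f2 <- make_fire(2L, matrix(c(20000, 0), 1), step, config = cfg)
  f2$pixels$new <- FALSE                     # no new pixels: empty fireline
  f2$fline <- active_fireline(f2$hull, matrix(0, 0, 2), cfg$fline_radius)
  f3 <- make_fire(3L, matrix(c(40000, 0), 1), step, config = cfg)
  f3$invalid <- TRUE
  state$fires <- list(f1, f2, f3)
  d <- tempfile()
  paths <- write_snapshot(state, d)
  per <- read_geojson_polygons(paths[["perimeter"]])
  expect_length(per$geoms, 2)                # invalid fire excluded
  fl <- jsonlite::fromJSON(readLines(paths[["fireline"]]),
                           simplifyVector = FALSE)
  expect_length(fl$features, 1)              # empty fireline absent
  # geometry round-trips through the file within coordinate precision
  g1 <- firetrackr:::project_to_lonlat(f1$hull$geom, cfg$proj)
  expect_equal(fg_area(per$geoms[[1]]), fg_area(g1), tolerance = 1e-9)
})

test_that("the large-fire product applies the 4 km2 threshold", {
  run <- default_fire_run(seed = 7, duration = 10)   # final size ~37 km2
  d <- tempfile()
  paths <- write_largefire_series(run$res$history, d, year = "2020")
  per <- jsonlite::fromJSON(readLines(paths[["perimeter"]]),
                            simplifyVector = FALSE)
  # one record per step from first detection onwards
  expect_gte(length(per$features), run$scn$duration)
  ids <- unique(vapply(per$features, function(f) f$properties$fid, 0))
  expect_equal(ids, 1)
  # a small fire is excluded: single-pixel fire never exceeds 4 km2
  cfg <- fed_config()
  step <- fed_step("20200801AM")
  state <- allfires_init(cfg)
  state$t <- step
  state$fires <- list(make_fire(1L, matrix(c(0, 0), 1), step, config = cfg))
  d2 <- tempfile()
  p2 <- write_largefire_series(list(`20200801AM` = state), d2, year = "2020")
  per2 <- jsonlite::fromJSON(readLines(p2[["perimeter"]]),
                             simplifyVector = FALSE)
  expect_length(per2$features, 0)            # valid empty file
})

test_that("summary series agrees with per-step snapshots and heritage counts", {
  run <- default_fire_run(seed = 7, duration = 8)
  d <- tempfile()
  paths <- write_summary(run$res$history, d, year = "2020")
  series <- utils::read.csv(paths[["series"]])
  expect_equal(nrow(series), length(run$res$history))
  for (k in c(1, 4, length(run$res$history))) {
    st <- run$res$history[[k]]
    agg <- summarize_state(st)
    expect_equal(series$n_fires[k], agg$n_fires)
    expect_equal(series$total_farea_km2[k], agg$total_farea_km2,
                 tolerance = 1e-9)
    nvalid <- sum(vapply(st$fires, function(f)
      !f$invalid && !is.null(f$hull), TRUE))
    expect_equal(series$n_fires[k], nvalid)
  }
  her <- utils::read.csv(paths[["heritage"]])
  expect_equal(nrow(her), nrow(run$state$heritages))
})

test_that("an empty season writes all-zero series and empty lists", {
  cfg <- fed_config()
  state <- allfires_init(cfg)
  steps <- step_sequence(fed_step("20200101AM"), fed_step("20200102PM"))
  history <- list()
  for (s in steps) {
    state <- advance(state, data.frame(
      lat = numeric(0), lon = numeric(0), frp = numeric(0),
      acq_date = as.Date(character(0)), acq_min = numeric(0),
      type = integer(0), confidence = character(0)), s)
    history[[format(s)]] <- state
  }
  d <- tempfile()
  paths <- write_summary(history, d, year = "2020")
  series <- utils::read.csv(paths[["series"]])
  expect_true(all(series$n_fires == 0))
  expect_true(all(series$total_farea_km2 == 0))
  her <- utils::read.csv(paths[["heritage"]])
  expect_equal(nrow(her), 0)
})
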