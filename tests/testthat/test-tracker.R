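# Cluster formation, fire assignment, merging, activity bookkeeping and
# tracker invariants on simulated scenarios.

test_that("single-linkage clustering matches the union-find oracle", {
  expect_length(cluster_pixels(matrix(0, 0, 2), 1000), 0)
  expect_equal(cluster_pixels(rbind(c(0, 0), c(300, 0)), 1000), c(1L, 1L))
  expect_equal(cluster_pixels(rbind(c(0, 0), c(5000, 0)), 1000), c(1L, 2L))
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(2:80, 1)
    pts <- cbind(runif(n, 0, 8000), runif(n, 0, 8000))
    linkage <- runif(1, 300, 2000)
    got <- cluster_pixels(pts, linkage)
    want <- brute_clusters(pts, linkage)
    # same partition (labels both ordered by first appearance)
    expect_equal(got, want)
  }
})

test_that("clusters attach within the type-dependent buffer of active fires only", {
  cfg <- fed_config()
  step <- fed_step("20200801AM")
  state <- allfires_init(cfg)
  state$t <- step
  forest <- make_fire(1L, rbind(c(0, 0), c(375, 0), c(0, 375), c(375, 375)),
                      step, config = cfg)
  forest$ftype <- "forest_wildfire"
  shrub <- make_fire(2L, rbind(c(50000, 0), c(50375, 0), c(50000, 375),
                               c(50375, 375)), step, config = cfg)
  shrub$ftype <- "shrub_wildfire"
  state$fires <- list(forest, shrub)

  # 500 m beyond the forest perimeter: within its 5 km buffer
  hit <- nearest_active_fire(matrix(c(375 + 187.5 + 500, 100), 1), state)
  expect_equal(hit$id, 1L)
  # 2 km from the shrub fire: outside its 1 km buffer
  hit2 <- nearest_active_fire(matrix(c(50375 + 187.5 + 2000, 100), 1), state)
  expect_true(is.na(hit2$id))
  # inactive fires never receive clusters
  state$fires[[1]]$isactive <- FALSE
  hit3 <- nearest_active_fire(matrix(c(375 + 187.5 + 500, 100), 1), state)
  expect_true(is.na(hit3$id))
})

test_that("apply_clusters appends to nearby fires and creates new ones elsewhere", {
  cfg <- fed_config()
  step <- fed_step("20200801AM")
  state <- allfires_init(cfg)
  state$t <- step
  f1 <- make_fire(1L, rbind(c(0, 0), c(375, 0), c(0, 375), c(375, 375)),
                  step, config = cfg)
  f1$ftype <- "forest_wildfire"
  f1$pixels$new <- FALSE
  state$fires <- list(f1)
  state$t <- step_succ(step)

  mkcl <- function(x, y) {
    ll <- fed_unproject(x, y, cfg$proj)
    data.frame(x = x, y = y, lon = ll[, 1], lat = ll[, 2], frp = 1,
               t = unclass(state$t), origin = NA_integer_,
               new = TRUE, ign = FALSE)
  }
  near <- mkcl(c(1200, 1575), c(0, 0))      # inside forest 5 km buffer
  far <- mkcl(c(90000, 90375), c(0, 0))     # far from everything
  state2 <- apply_clusters(state, list(near, far))
  expect_equal(state2$fids_expanded, 1L)
  expect_equal(state2$fids_new, 2L)
  expect_equal(nrow(state2$fires[[1]]$pixels), 6)
  expect_equal(unique(state2$fires[[2]]$pixels$origin), 2L)
  expect_true(all(state2$fires[[2]]$pixels$ign))
  # appended pixels keep the receiving fire id as origin, set once
  expect_equal(unique(state2$fires[[1]]$pixels$origin[5:6]), 1L)
  expect_equal(format(state2$fires[[1]]$t_ed), format(state2$t))
})

test_that("merge chains resolve transitively to the lowest id", {
  cfg <- fed_config()
  step <- fed_step("20200801AM")
  state <- allfires_init(cfg)
  state$t <- step
  f1 <- make_fire(1L, matrix(c(1500, 0), 1), step, config = cfg)
  f2 <- make_fire(2L, matrix(c(2800, 0), 1), step, config = cfg)
  f3 <- make_fire(3L, rbind(c(3600, 0), c(3400, 0)), step, config = cfg)
  state$fires <- list(f1, f2, f3)
  state$fids_expanded <- 3L
  out <- merge_grown_fires(state)
  expect_true(out$fires[[2]]$invalid)
  expect_true(out$fires[[3]]$invalid)
  expect_false(out$fires[[1]]$invalid)
  expect_equal(nrow(out$fires[[1]]$pixels), 4)   # all pixels end in fire 1
  expect_equal(nrow(out$fires[[2]]$pixels), 0)
  expect_equal(out$heritages[, "source"], c(3L, 2L))
  expect_equal(out$heritages[, "target"], c(2L, 1L))
  # heritage soundness: sources invalid, final target valid
  expect_true(all(vapply(out$heritages[, "source"],
                         function(i) out$fires[[i]]$invalid, TRUE)))
})

test_that("no overlaps leaves the heritage list unchanged", {
  cfg <- fed_config()
  step <- fed_step("20200801AM")
  state <- allfires_init(cfg)
  state$t <- step
  state$fires <- list(make_fire(1L, matrix(c(0, 0), 1), step, config = cfg),
                      make_fire(2L, matrix(c(30000, 0), 1), step,
                                config = cfg))
  state$fids_expanded <- c(1L, 2L)
  out <- merge_grown_fires(state)
  expect_equal(nrow(out$heritages), 0)
  expect_false(out$fires[[1]]$invalid)
})

test_that("fires expire after five days without new pixels and stay expired", {
  cfg <- fed_config()
  t0 <- fed_step("20200801AM")
  state <- allfires_init(cfg)
  state$t <- t0
  f <- make_fire(1L, matrix(c(0, 0), 1), t0, config = cfg)
  g <- make_fire(2L, matrix(c(20000, 0), 1), t0, config = cfg)
  g$invalid <- TRUE
  state$fires <- list(f, g)

  state$t <- step_succ(t0, 10L)       # exactly 5.0 days later
  s1 <- update_activity(state)
  expect_true(s1$fires[[1]]$isactive)
  expect_equal(s1$fires[[1]]$t_inactive, 5)

  state$t <- step_succ(t0, 11L)       # 5.5 days: beyond the limit
  s2 <- update_activity(state)
  expect_false(s2$fires[[1]]$isactive)
  expect_false(s2$fires[[2]]$isactive)  # invalid fires are never active
  expect_true(s2$fires[[2]]$invalid)
})

empty_records_df <- function() {
  data.frame(lat = numeric(0), lon = numeric(0), frp = numeric(0),
             acq_date = as.Date(character(0)), acq_min = numeric(0),
             type = integer(0), confidence = character(0))
}

test_that("advance handles empty batches and enforces step succession", {
  cfg <- fed_config()
  t0 <- fed_step("20200801AM")
  state <- allfires_init(cfg)
  state <- advance(state, empty_records_df(), t0)
  expect_length(state$fids_new, 0)
  expect_error(advance(state, empty_records_df(), step_succ(t0, 3L)),
               "does not follow")
  # one isolated cluster forms exactly one new fire
  rec <- data.frame(lat = 37.8, lon = -120.5, frp = 3,
                    acq_date = step_date(step_succ(t0)),
                    acq_min = 570, type = 0L, confidence = "nominal")
  state <- advance(state, rec, step_succ(t0))
  expect_length(state$fids_new, 1)
  expect_equal(nrow(state$fires[[1]]$pixels), 1)
})

test_that("tracker invariants hold on a simulated fire", {
  run <- default_fire_run(seed = 7, duration = 10)
  st <- run$state
  # pixel conservation: every ingested pixel in exactly one fire
  expect_equal(sum(vapply(st$fires, function(f) nrow(f$pixels), 0L)),
               nrow(run$recs))
  # monotone growth of the surviving fire
  areas <- c(); npix <- c()
  for (h in run$res$history) {
    if (length(h$fires) == 0) next
    f <- h$fires[[1]]
    if (!is.null(f$hull) && !f$invalid) {
      areas <- c(areas, f$hull$area)
      npix <- c(npix, nrow(f$pixels))
    }
  }
  expect_true(all(diff(areas) >= -1e-9))
  expect_true(all(diff(npix) >= 0))
  # heritage is acyclic: sources strictly greater than targets
  if (nrow(st$heritages) > 0)
    expect_true(all(st$heritages[, "source"] > st$heritages[, "target"]))
  # deterministic replay
  run2 <- default_fire_run(seed = 7, duration = 10)
  expect_true(isTRUE(all.equal(st, run2$state, tolerance = 0)))
})
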