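# Detection parsing, filtering and half-daily partitioning.

write_csv_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("latitude,longitude,frp,acq_date,acq_time,type,confidence",
               rows), path)
  path
}

test_that("valid rows map to records and malformed rows are rejected", {
  path <- write_csv_fixture(c(
    "37.0,-120.0,5.2,2020-08-01,0930,0,nominal",
    "95.0,-120.0,1.0,2020-08-01,0930,0,nominal",   # latitude out of range
    "37.0,-181.0,1.0,2020-08-01,0930,0,high",      # longitude out of range
    "36.5,-119.5,2.0,2020-08-01,2130,1,l"))
  expect_message(rec <- read_detections(path), "rejected 2")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$lat[1], 37.0)
  expect_equal(rec$frp[1], 5.2)
  expect_equal(rec$acq_min[1], 9 * 60 + 30)
  expect_equal(rec$confidence, c("nominal", "low"))
})

test_that("empty file with header gives empty record table", {
  path <- write_csv_fixture(character(0))
  rec <- read_detections(path)
  expect_equal(nrow(rec), 0)
})

test_that("missing required column is a fatal format error", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("latitude,longitude,frp,acq_date,acq_time,type",
               "37,-120,1,2020-08-01,0930,0"), path)
  expect_error(read_detections(path), "missing required column")
})

test_that("half-day windows are closed on the left in local time", {
  cfg <- fed_config(utc_offset = -8)
  # local 11:59 -> AM; local 12:00 -> PM; local 00:00 -> AM
  rec <- data.frame(lat = 37, lon = -120, frp = 1,
                    acq_date = as.Date("2020-08-01"),
                    acq_min = c(19 * 60 + 59, 20 * 60, 8 * 60),
                    type = 0L, confidence = "nominal")
  steps <- record_steps(rec, cfg)
  expect_equal(step_half(steps[[1]]), "AM")
  expect_equal(step_half(steps[[2]]), "PM")
  expect_equal(step_half(steps[[3]]), "AM")
  expect_equal(format(step_date(steps[[1]]), "%Y-%m-%d"), "2020-08-01")
})

test_that("filters drop non-vegetation, low-confidence (nrt) and out-of-roi records", {
  roi <- square_geom(-121, 37, 1)  # lon/lat degrees square
  rec <- data.frame(
    lat = c(37.5, 37.5, 37.5, 39.0),
    lon = c(-120.5, -120.5, -120.5, -120.5),
    frp = 1, acq_date = as.Date("2020-08-01"), acq_min = 600,
    type = c(0L, 1L, 0L, 0L),
    confidence = c("nominal", "nominal", "low", "high"))
  cfg <- fed_config(mode = "archive")
  out <- filter_records(rec, roi = roi, config = cfg)
  expect_equal(nrow(out), 2)          # type 1 and out-of-roi dropped
  cfg_nrt <- fed_config(mode = "nrt")
  out_nrt <- filter_records(rec, roi = roi, config = cfg_nrt)
  expect_equal(nrow(out_nrt), 1)      # low confidence also dropped
  # idempotence
  expect_identical(filter_records(out, roi = roi, config = cfg), out)
})

test_that("step sequences enumerate every half day", {
  s <- fed_step("20200101AM")
  expect_length(step_sequence(s, step_succ(s)), 2)
  expect_length(step_sequence(s, fed_step("20200102AM")), 3)
  expect_length(step_sequence(fed_step("20190101AM"),
                              fed_step("20191231PM")), 730)
  expect_length(step_sequence(fed_step("20200101AM"),
                              fed_step("20201231PM")), 732)
  expect_error(step_sequence(step_succ(s), s), "after")
})

test_that("every filtered record lands in exactly one batch", {
  set.seed(42)
  n <- 60
  rec <- data.frame(
    lat = runif(n, 37, 38), lon = runif(n, -121, -120), frp = 1,
    acq_date = as.Date("2020-08-01") + sample(0:4, n, TRUE),
    acq_min = sample(0:1439, n, TRUE), type = 0L, confidence = "nominal")
  cfg <- fed_config()
  steps <- step_sequence(fed_step("20200731AM"), fed_step("20200806PM"))
  batches <- partition_records(rec, steps, cfg)
  expect_equal(sum(vapply(batches, nrow, 0L)), n)
  # and the same record never appears twice
  allrows <- do.call(rbind, batches)
  expect_equal(nrow(unique(allrows)), nrow(unique(rec)))
})
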