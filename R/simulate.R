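# Seeded synthetic-detection simulator.
#
# The simulator is an observation-process emulator, not a fire-behaviour
# model: a fire footprint grows as an ellipse (closed-form ground truth)
# oriented by a wind direction, and the newly burned ring at each half-day
# is sampled onto a 375 m detection lattice with an imperfect detection
# probability, positional jitter and log-normally distributed FRP. Static
# hotspots emit 1-3 detections per step at a fixed location. All
# randomness flows from one seed per scenario.

#' Fire-spread scenario
#'
#' Defines a synthetic spreading fire: ignition point(s), timing, growth
#' rates and the detection process. Defaults emulate the half-daily VIIRS
#' observation geometry (375 m detection lattice, ~1:30 am/pm overpasses).
#'
#' @param ignition Matrix (or length-2 vector) of ignition lon/lat
#'   coordinates; multiple rows grow as a union of ellipses.
#' @param start Start step (\code{\link{fed_step}}).
#' @param duration Number of half-daily steps of growth.
#' @param rate_along,rate_cross Semi-axis growth rates in metres per
#'   half-day along and across the wind direction.
#' @param wind_deg Wind direction in degrees (math convention, from +x).
#' @param detect_prob Probability that a lattice node in the newly burned
#'   ring is detected, in (0, 1].
#' @param spacing Detection lattice spacing in metres (375 m).
#' @param jitter_sd Positional jitter standard deviation in metres.
#' @param frp_meanlog,frp_sdlog Log-normal FRP parameters (MW).
#' @param seed Integer seed; every random draw in the scenario derives
#'   from it.
#' @return A list of class \code{fed_scenario}.
#' @export
spread_scenario <- function(ignition = c(-120.5, 37.8),
                            start = fed_step("20200801AM"),
                            duration = 12,
                            rate_along = 400, rate_cross = 200,
                            wind_deg = 30,
                            detect_prob = 0.95,
                            spacing = 375,
                            jitter_sd = 50,
                            frp_meanlog = log(5), frp_sdlog = 0.8,
                            seed = 1L) {
  ignition <- coerce_pts(ignition)
  stopifnot(duration >= 1, rate_along >= 0, rate_cross >= 0,
            detect_prob > 0, detect_prob <= 1, spacing > 0)
  structure(list(ignition = ignition, start = start, duration = duration,
                 rate_along = rate_along, rate_cross = rate_cross,
                 wind_deg = wind_deg, detect_prob = detect_prob,
                 spacing = spacing, jitter_sd = jitter_sd,
                 frp_meanlog = frp_meanlog, frp_sdlog = frp_sdlog,
                 seed = as.integer(seed)),
            class = "fed_scenario")
}

ellipse_ring <- function(center, a, b, theta, n = 72) {
  t <- 2 * pi * (0:(n - 1)) / n
  ex <- a * cos(t); ey <- b * sin(t)
  cbind(center[1] + ex * cos(theta) - ey * sin(theta),
        center[2] + ex * sin(theta) + ey * cos(theta))
}

#' Simulate elliptical fire spread
#'
#' At step k (1-based) each ignition's footprint is an ellipse with
#' semi-axes \code{k * rate_along} and \code{k * rate_cross} oriented by
#' the wind; the regional footprint is the union over ignitions. A minimal
#' ignition disc (half the lattice spacing) keeps the step-0 footprint
#' non-degenerate when rates are zero.
#'
#' @param scn A \code{\link{spread_scenario}}.
#' @param proj Projection parameters (footprints are built in metres).
#' @return List of class \code{fed_truth}: \code{steps} (list of
#'   \code{fed_step}), \code{footprints} (list of \code{fgeom}, nested and
#'   cumulative), \code{scenario}.
#' @export
simulate_spread <- function(scn, proj = fed_config()$proj) {
  ign_xy <- fed_project(scn$ignition[, 1], scn$ignition[, 2], proj)
  theta <- scn$wind_deg * pi / 180
  r0 <- scn$spacing / 2
  steps <- vector("list", scn$duration)
  fps <- vector("list", scn$duration)
  for (k in seq_len(scn$duration)) {
    steps[[k]] <- step_succ(scn$start, k - 1L)
    a <- max(k * scn$rate_along, r0)
    b <- max(k * scn$rate_cross, r0)
    rings <- lapply(seq_len(nrow(ign_xy)), function(i)
      ellipse_ring(ign_xy[i, ], a, b, theta))
    fps[[k]] <- if (length(rings) == 1) fgeom(rings) else {
      u <- union_convex(rings)
      if (fg_is_empty(u)) fgeom(rings) else u
    }
  }
  structure(list(steps = steps, footprints = fps, scenario = scn,
                 proj = proj),
            class = "fed_truth")
}

#' Sample half-daily detections from a truth sequence
#'
#' Lays the detection lattice over the newly burned ring of each step
#' (footprint k minus footprint k-1; the whole footprint at the first
#' step), keeps each node with the detection probability, jitters the kept
#' positions and draws FRP values. Acquisition timestamps sit at the
#' nominal overpass times (01:30 / 13:30 local, converted to UTC).
#'
#' @param truth A \code{fed_truth} from \code{\link{simulate_spread}}.
#' @param config A \code{\link{fed_config}} (UTC offset, projection).
#' @return A record table in the \code{\link{read_detections}} layout with
#'   all rows of all steps, ordered by step.
#' @export
sample_detections <- function(truth, config = fed_config()) {
  scn <- truth$scenario
  set.seed(scn$seed)
  sp <- scn$spacing
  out <- list()
  for (k in seq_along(truth$steps)) {
    g <- truth$footprints[[k]]
    bb <- fg_bbox(g)
    gx <- seq(floor(bb[1] / sp) * sp, ceiling(bb[3] / sp) * sp, by = sp)
    gy <- seq(floor(bb[2] / sp) * sp, ceiling(bb[4] / sp) * sp, by = sp)
    nodes <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    inside <- fg_contains(g, nodes)
    if (k > 1) inside <- inside & !fg_contains(truth$footprints[[k - 1]], nodes)
    nodes <- nodes[inside, , drop = FALSE]
    if (nrow(nodes) == 0) next
    kept <- stats::runif(nrow(nodes)) <= scn$detect_prob
    nodes <- nodes[kept, , drop = FALSE]
    if (nrow(nodes) == 0) next
    nodes[, 1] <- nodes[, 1] + stats::rnorm(nrow(nodes), 0, scn$jitter_sd)
    nodes[, 2] <- nodes[, 2] + stats::rnorm(nrow(nodes), 0, scn$jitter_sd)
    ll <- fed_unproject(nodes[, 1], nodes[, 2], truth$proj)
    frp <- stats::rlnorm(nrow(nodes), scn$frp_meanlog, scn$frp_sdlog)
    out[[length(out) + 1]] <-
      step_records(ll, frp, truth$steps[[k]], config)
  }
  if (length(out) == 0) return(empty_records())
  do.call(rbind, out)
}

# Build detection records at the nominal 01:30/13:30 local overpass of a
# step, converted back to UTC with the configured offset.
step_records <- function(lonlat, frp, step, config) {
  local_min <- if (step_half(step) == "AM") 90 else 810  # 1:30 / 13:30
  utc_min <- local_min - 60 * config$utc_offset
  day <- as.integer(unclass(step) %/% 2L)
  dayshift <- floor(utc_min / 1440)
  utc_min <- utc_min - 1440 * dayshift
  data.frame(lat = lonlat[, 2], lon = lonlat[, 1], frp = frp,
             acq_date = as.Date(day + dayshift, origin = "1970-01-01"),
             acq_min = utc_min, type = 0L, confidence = "nominal",
             stringsAsFactors = FALSE)
}

#' Simulate a persistent static hotspot
#'
#' Emits 1-3 detections per step at a fixed location (small positional
#' jitter) for a run of consecutive steps, emulating gas flares and other
#' persistent industrial heat sources.
#'
#' @param loc Length-2 lon/lat vector.
#' @param start First \code{\link{fed_step}}.
#' @param n_steps Number of consecutive half-daily steps.
#' @param seed Integer seed.
#' @param jitter_sd Positional jitter sd in metres.
#' @param config A \code{\link{fed_config}}.
#' @return A record table in the \code{\link{read_detections}} layout.
#' @export
simulate_static_source <- function(loc, start, n_steps, seed = 1L,
                                   jitter_sd = 60, config = fed_config()) {
  stopifnot(n_steps >= 1)
  set.seed(as.integer(seed))
  xy <- fed_project(loc[1], loc[2], config$proj)
  out <- list()
  for (k in seq_len(n_steps)) {
    n <- sample(1:3, 1)
    px <- xy[1, 1] + stats::rnorm(n, 0, jitter_sd)
    py <- xy[1, 2] + stats::rnorm(n, 0, jitter_sd)
    ll <- fed_unproject(px, py, config$proj)
    frp <- stats::rlnorm(n, log(2), 0.5)
    out[[length(out) + 1]] <-
      step_records(ll, frp, step_succ(start, k - 1L), config)
  }
  do.call(rbind, out)
}

#' Synthetic land-cover and fuel-moisture rasters
#'
#' Builds a blockwise land-cover grid with requested class area fractions
#' (vertical bands spanning the extent) and a smooth fuel-moisture field
#' around a configurable mean.
#'
#' @param extent Numeric \code{c(xmin, ymin, xmax, ymax)} in projected
#'   metres.
#' @param composition Named numeric vector of class fractions (names from
#'   \code{\link{landcover_classes}}), summing to 1.
#' @param fm_mean,fm_amplitude Mean and spatial amplitude of the
#'   fuel-moisture field (percent).
#' @param cellsize Cell size in metres.
#' @param seed Integer seed (reserved; the fields are deterministic).
#' @return List with \code{lct} and \code{fm1000} rasters
#'   (\code{\link{fed_raster}}).
#' @export
synth_rasters <- function(extent, composition = c(forest = 1),
                          fm_mean = 15, fm_amplitude = 1,
                          cellsize = 375, seed = 1L) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("synth_rasters: composition fractions must sum to 1")
  cls <- landcover_classes()
  if (!all(names(composition) %in% names(cls)))
    stop("synth_rasters: unknown land-cover class name")
  ncol_ <- max(2L, ceiling((extent[3] - extent[1]) / cellsize))
  nrow_ <- max(2L, ceiling((extent[4] - extent[2]) / cellsize))
  # vertical bands with widths proportional to the fractions
  edges <- round(cumsum(composition) * ncol_)
  codes <- integer(ncol_)
  lo <- 1
  for (i in seq_along(composition)) {
    hi <- edges[i]
    if (hi >= lo) codes[lo:hi] <- cls[[names(composition)[i]]]
    lo <- hi + 1
  }
  codes[codes == 0] <- cls[[names(composition)[length(composition)]]]
  lct <- fed_raster(matrix(rep(codes, each = nrow_), nrow = nrow_),
                    extent[1], extent[2], cellsize)
  cx <- extent[1] + (seq_len(ncol_) - 0.5) * cellsize
  cy <- extent[2] + (seq_len(nrow_) - 0.5) * cellsize
  span <- max(extent[3] - extent[1], 1)
  fm_vals <- outer(rev(cy), cx, function(y, x)
    fm_mean + fm_amplitude * sin(2 * pi * x / span) * cos(2 * pi * y / span))
  fm <- fed_raster(fm_vals, extent[1], extent[2], cellsize)
  list(lct = lct, fm1000 = fm)
}

#' Write scenario detections as a detection CSV
#'
#' Serialises a record table in the dialect \code{\link{read_detections}}
#' reads (columns per \code{config$columns}).
#'
#' @param records Record table.
#' @param path Output CSV path.
#' @param config A \code{\link{fed_config}}.
#' @return \code{path}, invisibly.
#' @export
write_detections_csv <- function(records, path, config = fed_config()) {
  cm <- config$columns
  out <- data.frame(
    records$lat, records$lon, records$frp,
    format(records$acq_date, "%Y-%m-%d"),
    sprintf("%02d%02d", records$acq_min %/% 60, records$acq_min %% 60),
    records$type, records$confidence,
    stringsAsFactors = FALSE
  )
  names(out) <- unlist(cm[c("lat", "lon", "frp", "date", "time", "type",
                            "confidence")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
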