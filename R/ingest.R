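# Parsing, filtering and time-partitioning of active-fire detection
# records. The input dialect is a delimited table with configurable column
# names (latitude, longitude, FRP in MW, acquisition date and UTC time,
# thermal-anomaly type code, confidence class), matching the monthly VIIRS
# I-band fire-location product layout.

#' Read active-fire detection records
#'
#' Parses a detection CSV into a record table. Malformed rows (unparseable
#' coordinates, dates or times, out-of-range latitude/longitude, negative
#' FRP) are dropped with a message reporting the count.
#'
#' @param path CSV file path.
#' @param config A \code{\link{fed_config}}; \code{config$columns} maps the
#'   required fields to column names. The time column accepts
#'   \code{"HHMM"}, \code{"HH:MM"} or \code{"HH:MM:SS"} UTC.
#' @return A data.frame with columns \code{lat}, \code{lon}, \code{frp},
#'   \code{acq_date} (Date), \code{acq_min} (minutes since UTC midnight),
#'   \code{type} (integer anomaly code) and \code{confidence}
#'   (\code{"low"}, \code{"nominal"} or \code{"high"}).
#' @export
read_detections <- function(path, config = fed_config()) {
  if (!file.exists(path)) stop("read_detections: file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cm <- config$columns
  missing_cols <- setdiff(unlist(cm), names(raw))
  if (length(missing_cols))
    stop("read_detections: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  if (n == 0) return(empty_records())
  parse_time <- function(x) {
    x <- trimws(as.character(x))
    x[x == ""] <- NA
    has_colon <- grepl(":", x)
    out <- rep(NA_real_, length(x))
    hc <- which(has_colon)
    if (length(hc)) {
      parts <- strsplit(x[hc], ":")
      out[hc] <- vapply(parts, function(p)
        suppressWarnings(as.numeric(p[1]) * 60 + as.numeric(p[2])), 0)
    }
    nc <- which(!has_colon & !is.na(x))
    if (length(nc)) {
      v <- suppressWarnings(as.numeric(x[nc]))
      out[nc] <- (v %/% 100) * 60 + v %% 100
    }
    out[out < 0 | out >= 1440] <- NA
    out
  }
  conf <- tolower(trimws(as.character(raw[[cm$confidence]])))
  conf_map <- c(l = "low", low = "low", n = "nominal", nominal = "nominal",
                h = "high", high = "high")
  rec <- data.frame(
    lat = suppressWarnings(as.numeric(raw[[cm$lat]])),
    lon = suppressWarnings(as.numeric(raw[[cm$lon]])),
    frp = suppressWarnings(as.numeric(raw[[cm$frp]])),
    acq_date = suppressWarnings(as.Date(as.character(raw[[cm$date]]))),
    acq_min = parse_time(raw[[cm$time]]),
    type = suppressWarnings(as.integer(raw[[cm$type]])),
    confidence = unname(conf_map[conf]),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(rec$lat) & !is.na(rec$lon) & !is.na(rec$frp) &
    !is.na(rec$acq_date) & !is.na(rec$acq_min) & !is.na(rec$type) &
    rec$lat >= -90 & rec$lat <= 90 & rec$lon >= -180 & rec$lon <= 180 &
    rec$frp >= 0
  if (any(!ok))
    message(sprintf("read_detections: rejected %d malformed row(s)",
                    sum(!ok)))
  rec[ok, , drop = FALSE]
}

empty_records <- function() {
  data.frame(lat = numeric(0), lon = numeric(0), frp = numeric(0),
             acq_date = as.Date(character(0)), acq_min = numeric(0),
             type = integer(0), confidence = character(0),
             stringsAsFactors = FALSE)
}

#' Half-daily time step of each record
#'
#' Converts UTC acquisition times to local time with the fixed region UTC
#' offset (no daylight saving) and assigns the half-day window: AM covers
#' local [00:00, 12:00), PM [12:00, 24:00) (closed on the left).
#'
#' @param records Record table from \code{\link{read_detections}}.
#' @param config A \code{\link{fed_config}}.
#' @return List of \code{\link{fed_step}} objects, one per record.
#' @export
record_steps <- function(records, config = fed_config()) {
  lmin <- records$acq_min + 60 * config$utc_offset
  dayshift <- floor(lmin / 1440)
  lmin <- lmin - 1440 * dayshift
  day <- as.integer(records$acq_date) + dayshift
  idx <- 2L * day + as.integer(lmin >= 720)
  lapply(idx, step_from_index)
}

record_step_index <- function(records, config) {
  lmin <- records$acq_min + 60 * config$utc_offset
  dayshift <- floor(lmin / 1440)
  lmin <- lmin - 1440 * dayshift
  2L * (as.integer(records$acq_date) + dayshift) + as.integer(lmin >= 720)
}

#' Filter detection records
#'
#' Applies the static filters: thermal-anomaly type 0 (presumed vegetation
#' fire), containment in the region-of-interest polygon, and optionally a
#' half-day time window. In \code{nrt} mode only nominal or high confidence
#' detections are kept (the near-real-time product carries less quality
#' assurance). Filtering is idempotent.
#'
#' @param records Record table from \code{\link{read_detections}}.
#' @param roi An \code{fgeom} in geographic lon/lat coordinates, or NULL to
#'   skip the spatial filter.
#' @param step A \code{\link{fed_step}} restricting records to one half-day
#'   window, or NULL.
#' @param config A \code{\link{fed_config}} (supplies the mode and UTC
#'   offset).
#' @return The filtered record table.
#' @export
filter_records <- function(records, roi = NULL, step = NULL,
                           config = fed_config()) {
  keep <- records$type == 0L
  if (config$mode == "nrt")
    keep <- keep & records$confidence %in% c("nominal", "high")
  if (!is.null(roi) && nrow(records) > 0) {
    pts <- cbind(records$lon, records$lat)
    keep <- keep & fg_covers(roi, pts, tol = 1e-9)
  }
  if (!is.null(step))
    keep <- keep & record_step_index(records, config) == unclass(step)
  records[keep, , drop = FALSE]
}

#' Partition records into half-daily batches
#'
#' Splits a filtered record table by time step; every record whose step
#' falls inside the sequence appears in exactly one batch.
#'
#' @param records Filtered record table.
#' @param steps List of \code{\link{fed_step}} from
#'   \code{\link{step_sequence}}.
#' @param config A \code{\link{fed_config}}.
#' @return Named list of record tables, one per step (names are formatted
#'   steps, e.g. \code{"20200908PM"}); steps without records get empty
#'   tables.
#' @export
partition_records <- function(records, steps, config = fed_config()) {
  idx <- record_step_index(records, config)
  out <- lapply(steps, function(s) records[idx == unclass(s), , drop = FALSE])
  names(out) <- vapply(steps, format, "")
  out
}
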