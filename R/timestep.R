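#' Half-daily time steps
#'
#' The tracker's native clock is the half-daily overpass cadence (~1:30 am
#' and ~1:30 pm local time). A time step is a calendar day plus an AM/PM
#' half, stored internally as an integer index (2 x days since 1970-01-01,
#' +1 for PM) so that steps are totally ordered and the successor of
#' (d, AM) is (d, PM) and of (d, PM) is (d+1, AM).
#'
#' @param date A \code{Date} (or string \code{"YYYY-MM-DD"} /
#'   \code{"YYYYMMDD"}), or a compact step string \code{"YYYYMMDDAM"} /
#'   \code{"YYYYMMDDPM"} in which case \code{half} is ignored.
#' @param half \code{"AM"} or \code{"PM"}.
#' @return An object of class \code{fed_step} (an integer with attributes).
#' @examples
#' fed_step("20200908PM")
#' fed_step(as.Date("2020-01-01"), "AM")
#' @export
fed_step <- function(date, half = c("AM", "PM")) {
  if (is.character(date) && length(date) == 1 &&
      grepl("^[0-9]{8}(AM|PM)$", date)) {
    half <- substr(date, 9, 10)
    date <- as.Date(substr(date, 1, 8), format = "%Y%m%d")
  } else {
    half <- match.arg(half)
    if (is.character(date)) {
      date <- if (grepl("^[0-9]{8}$", date))
        as.Date(date, format = "%Y%m%d") else as.Date(date)
    }
  }
  stopifnot(inherits(date, "Date"), !is.na(date))
  idx <- 2L * as.integer(date) + ifelse(half == "PM", 1L, 0L)
  structure(idx, class = "fed_step")
}

step_from_index <- function(idx) structure(as.integer(idx), class = "fed_step")

#' @export
format.fed_step <- function(x, ...) {
  idx <- unclass(x)
  d <- as.Date(idx %/% 2L, origin = "1970-01-01")
  paste0(format(d, "%Y%m%d"), ifelse(idx %% 2L == 1L, "PM", "AM"))
}

#' @export
print.fed_step <- function(x, ...) {
  cat("<fed_step>", format(x), "\n")
  invisible(x)
}

#' @export
as.character.fed_step <- function(x, ...) format(x)

#' Step arithmetic and comparison helpers
#'
#' @param step A \code{fed_step}.
#' @param n Integer number of half-day steps.
#' @return \code{step_succ} returns the following step; \code{step_date} the
#'   calendar day; \code{step_half} \code{"AM"} or \code{"PM"};
#'   \code{step_diff_days} the signed difference \code{a - b} in days
#'   (half-steps count 0.5).
#' @export
step_succ <- function(step, n = 1L) step_from_index(unclass(step) + as.integer(n))

#' @rdname step_succ
#' @export
step_date <- function(step) as.Date(unclass(step) %/% 2L, origin = "1970-01-01")

#' @rdname step_succ
#' @export
step_half <- function(step) ifelse(unclass(step) %% 2L == 1L, "PM", "AM")

#' @rdname step_succ
#' @param a,b \code{fed_step} objects.
#' @export
step_diff_days <- function(a, b) (unclass(a) - unclass(b)) / 2

#' Ordered sequence of half-daily steps
#'
#' Every half-day between \code{start} and \code{end} inclusive; a full
#' calendar year (Jan 1 AM to Dec 31 PM) yields 730 steps (732 in leap
#' years).
#'
#' @param start,end \code{fed_step} objects with \code{start <= end}.
#' @return List of \code{fed_step}.
#' @export
step_sequence <- function(start, end) {
  i0 <- unclass(start); i1 <- unclass(end)
  if (i0 > i1) stop("step_sequence: start is after end")
  lapply(seq.int(i0, i1), step_from_index)
}
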