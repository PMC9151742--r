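# Minimal regular-grid raster container with plain-text (ESRI ASCII grid)
# input/output, used for the merged 7-class land-cover grid and the coarse
# 1000-hr dead fuel moisture field. Grids live on the same projected
# metre plane as the vector geometry.

#' Land-cover class codes
#'
#' Integer codes of the seven merged land-cover classes used for fire-type
#' classification.
#'
#' @return Named integer vector.
#' @export
landcover_classes <- function() {
  c(water = 1L, urban = 2L, barren = 3L, forest = 4L, shrub = 5L,
    grassland = 6L, agriculture = 7L)
}

#' Regular raster grid
#'
#' @param values Numeric matrix, row 1 = northernmost row (map order).
#' @param xmin,ymin Coordinates of the lower-left corner of the grid
#'   (metres, projected plane).
#' @param cellsize Cell edge length in metres.
#' @return An object of class \code{fed_raster}.
#' @export
fed_raster <- function(values, xmin, ymin, cellsize) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, nrow = nrow(values),
                 ncol = ncol(values)),
            class = "fed_raster")
}

#' @export
print.fed_raster <- function(x, ...) {
  cat(sprintf("<fed_raster> %d x %d cells of %g m, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$xmin, x$ymin))
  invisible(x)
}

#' Sample a raster at point locations
#'
#' Nearest-cell lookup; points outside the grid return NA.
#'
#' @param r A \code{\link{fed_raster}}.
#' @param pts 2-column matrix of projected coordinates (metres).
#' @return Numeric vector of cell values.
#' @export
raster_sample <- function(r, pts) {
  pts <- coerce_pts(pts)
  col <- floor((pts[, 1] - r$xmin) / r$cellsize) + 1
  row_from_bottom <- floor((pts[, 2] - r$ymin) / r$cellsize) + 1
  row <- r$nrow - row_from_bottom + 1
  ok <- col >= 1 & col <= r$ncol & row >= 1 & row <= r$nrow
  out <- rep(NA_real_, nrow(pts))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

# Coordinates of all cell centres intersecting a bounding box.
raster_centres_in_bbox <- function(r, bb) {
  cx <- r$xmin + (seq_len(r$ncol) - 0.5) * r$cellsize
  cy <- r$ymin + (seq_len(r$nrow) - 0.5) * r$cellsize  # bottom-up
  cx <- cx[cx >= bb[1] - r$cellsize & cx <= bb[3] + r$cellsize]
  cy <- cy[cy >= bb[2] - r$cellsize & cy <= bb[4] + r$cellsize]
  if (length(cx) == 0 || length(cy) == 0) return(matrix(0, 0, 2))
  cbind(rep(cx, times = length(cy)), rep(cy, each = length(cx)))
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format (\code{ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value} header followed by rows north to
#' south).
#'
#' @param path File path.
#' @param r A \code{\link{fed_raster}}.
#' @return \code{read_ascii_grid} returns a \code{fed_raster};
#'   \code{write_ascii_grid} returns \code{path} invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[a-zA-Z]", trimws(lines[i]))) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("read_ascii_grid: missing header fields")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("read_ascii_grid: cell count does not match header")
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  fed_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", r$ncol), paste("nrows", r$nrow),
    paste("xllcorner", format(r$xmin, digits = 15)),
    paste("yllcorner", format(r$ymin, digits = 15)),
    paste("cellsize", format(r$cellsize, digits = 15)),
    "NODATA_value -9999"
  ), con)
  vals <- r$values
  vals[is.na(vals)] <- -9999
  for (i in seq_len(r$nrow))
    writeLines(paste(format(vals[i, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}
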