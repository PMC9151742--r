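#' Tracker configuration
#'
#' Builds the configuration list that controls every stage of the tracking
#' system: perimeter delineation, clustering, fire-to-cluster assignment,
#' activity bookkeeping, fire-type classification and the static-source
#' filter. All distance parameters are in metres on the equal-area projected
#' plane; areas are in km2.
#'
#' @param alpha Alpha-shape disk radius in metres used for perimeter
#'   delineation. Default 1000 m.
#' @param pixel_buffer Outward buffer in metres applied to the concave hull,
#'   half the 375 m nadir cross-track pixel width. Default 187.5 m.
#' @param fline_radius Radius in metres around newly detected pixels within
#'   which perimeter segments count as the active fire front. Default 500 m.
#' @param linkage Single-linkage distance in metres used to cluster the new
#'   pixels of one time step. Default 1000 m.
#' @param buffer_forest,buffer_other Extended-area radial buffers in metres
#'   for forest fires (5 km) and all other fire types (1 km). A cluster (or a
#'   grown fire) within this distance of an active fire's perimeter is
#'   attached to (merged with) it.
#' @param inactive_days A fire with no new pixels for more than this many
#'   days becomes inactive and stops receiving clusters. Default 5.
#' @param large_fire_km2 Final-area threshold in km2 above which a fire is
#'   included in the large-fire time-series product. Default 4.
#' @param static_area_km2,static_density Static-source filter: a fire smaller
#'   than \code{static_area_km2} (km2) whose cumulative pixel density exceeds
#'   \code{static_density} (pixels per km2) is flagged invalid. Defaults 20
#'   and 20.
#' @param static_filter Logical; apply the static-source filter during
#'   tracking. Default TRUE.
#' @param fm_threshold 1000-hr dead fuel moisture (percent) separating
#'   wildfire (>= threshold) from management fire (< threshold) for forest,
#'   shrub and grassland fires. Default 12.
#' @param fm_wildfire_ge Logical; if TRUE (default) fuel moisture at or above
#'   the threshold maps to the wildfire class. The classification table is
#'   printed this way even though prescribed burns tend to occur under moister
#'   coarse fuels; the direction is exposed here so users can flip it.
#' @param utc_offset Fixed offset in hours added to UTC acquisition times to
#'   obtain local time for the half-day windows (no DST). Default -8
#'   (Pacific standard time).
#' @param mode Either \code{"archive"} or \code{"nrt"}. In nrt mode only
#'   nominal/high confidence detections are used.
#' @param proj Projection parameters, see \code{\link{fed_project}}. Default
#'   is an Albers equal-area conic centred on California.
#' @param arc_segments Number of segments used to discretise a full circle
#'   when buffering hull polygons. Default 16 (per vertex arc resolution).
#' @param circle_segments Number of segments for the 1-2 pixel circular
#'   perimeter fallback. Default 128.
#' @param columns Column-name map for the detection CSV dialect, see
#'   \code{\link{read_detections}}.
#'
#' @return A list of class \code{fed_config}.
#' @export
fed_config <- function(alpha = 1000,
                       pixel_buffer = 187.5,
                       fline_radius = 500,
                       linkage = 1000,
                       buffer_forest = 5000,
                       buffer_other = 1000,
                       inactive_days = 5,
                       large_fire_km2 = 4,
                       static_area_km2 = 20,
                       static_density = 20,
                       static_filter = TRUE,
                       fm_threshold = 12,
                       fm_wildfire_ge = TRUE,
                       utc_offset = -8,
                       mode = c("archive", "nrt"),
                       proj = NULL,
                       arc_segments = 16,
                       circle_segments = 128,
                       columns = NULL) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, pixel_buffer >= 0, fline_radius > 0, linkage > 0)
  if (is.null(proj)) {
    proj <- list(lon0 = -120, lat0 = 0, lat1 = 34, lat2 = 40.5,
                 R = 6370997)
  }
  if (is.null(columns)) {
    columns <- list(lat = "latitude", lon = "longitude", frp = "frp",
                    date = "acq_date", time = "acq_time", type = "type",
                    confidence = "confidence")
  }
  structure(list(
    alpha = alpha, pixel_buffer = pixel_buffer, fline_radius = fline_radius,
    linkage = linkage, buffer_forest = buffer_forest,
    buffer_other = buffer_other, inactive_days = inactive_days,
    large_fire_km2 = large_fire_km2, static_area_km2 = static_area_km2,
    static_density = static_density, static_filter = static_filter,
    fm_threshold = fm_threshold, fm_wildfire_ge = fm_wildfire_ge,
    utc_offset = utc_offset, mode = mode, proj = proj,
    arc_segments = arc_segments, circle_segments = circle_segments,
    columns = columns
  ), class = "fed_config")
}

#' Extended-area buffer for a fire type
#'
#' Forest fires receive a 5 km attachment/merge buffer, all other types 1 km.
#' Fires not yet classified fall back to the non-forest buffer.
#'
#' @param ftype Fire-type string (see \code{\link{classify_fire_type}}) or NA.
#' @param config A \code{\link{fed_config}}.
#' @return Buffer distance in metres.
#' @export
type_buffer <- function(ftype, config) {
  if (length(ftype) == 1 && !is.na(ftype) && ftype == "forest_wildfire")
    return(config$buffer_forest)
  if (length(ftype) == 1 && !is.na(ftype) && ftype == "forest_management")
    return(config$buffer_forest)
  config$buffer_other
}
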