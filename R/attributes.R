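# Per-fire attributes: dominant land cover, fire-type classification,
# the static-source flag, and the scalar property set refreshed at each
# time step.

#' Dominant land cover within a fire perimeter
#'
#' Modal land-cover class over the grid cells whose centres fall inside the
#' hull. When the hull is so small that no cell centre falls inside, the
#' class at the hull centroid is used. Ties are broken towards the smaller
#' class code for determinism.
#'
#' @param hull A \code{\link{fire_hull}} or \code{fgeom}.
#' @param grid A \code{\link{fed_raster}} of class codes (see
#'   \code{\link{landcover_classes}}).
#' @return Land-cover class name (character scalar).
#' @export
dominant_landcover <- function(hull, grid) {
  g <- if (inherits(hull, "fed_hull")) hull$geom else hull
  cls <- landcover_classes()
  ctr <- raster_centres_in_bbox(grid, fg_bbox(g))
  codes <- numeric(0)
  if (nrow(ctr) > 0) {
    inside <- fg_contains(g, ctr)
    codes <- raster_sample(grid, ctr[inside, , drop = FALSE])
    codes <- codes[!is.na(codes)]
  }
  if (length(codes) == 0) {
    code <- raster_sample(grid, matrix(fg_centroid(g), ncol = 2))
    if (is.na(code)) stop("dominant_landcover: hull outside land-cover grid")
    codes <- code
  }
  tab <- table(codes)
  best <- as.numeric(names(tab)[tab == max(tab)])
  names(cls)[match(min(best), cls)]
}

#' Fire-type classification
#'
#' Maps the dominant land-cover class and the 1000-hr dead fuel moisture at
#' ignition to a fire type. Forest, shrub and grassland fires split into
#' wildfire (fuel moisture at or above the threshold, 12 percent by
#' default) and management fire (below); agriculture and urban map to their
#' own types; water and barren to "other".
#'
#' @param lct Land-cover class name (one of
#'   \code{names(\link{landcover_classes}())}).
#' @param fm1000 1000-hr dead fuel moisture in percent at ignition; may be
#'   NA for classes that do not use it.
#' @param config A \code{\link{fed_config}} (controls the threshold and its
#'   direction).
#' @return One of \code{"forest_wildfire"}, \code{"forest_management"},
#'   \code{"shrub_wildfire"}, \code{"shrub_management"},
#'   \code{"agriculture"}, \code{"urban"}, \code{"other"}.
#' @export
classify_fire_type <- function(lct, fm1000 = NA_real_, config = fed_config()) {
  if (!lct %in% names(landcover_classes()))
    stop("classify_fire_type: unknown land-cover class: ", lct)
  if (lct %in% c("agriculture")) return("agriculture")
  if (lct %in% c("urban")) return("urban")
  if (lct %in% c("water", "barren")) return("other")
  if (is.na(fm1000))
    stop("classify_fire_type: fm1000 required for class ", lct)
  wild <- if (config$fm_wildfire_ge) fm1000 >= config$fm_threshold
          else fm1000 < config$fm_threshold
  if (lct == "forest") {
    if (wild) "forest_wildfire" else "forest_management"
  } else {  # shrub or grassland
    if (wild) "shrub_wildfire" else "shrub_management"
  }
}

#' Static-source test
#'
#' A fire smaller than 20 km2 with a cumulative pixel density above 20
#' pixels per km2 is a persistent static heat source (gas flares,
#' industrial sites) rather than a spreading vegetation fire.
#'
#' @param farea Fire area in km2.
#' @param npix Cumulative pixel count since ignition.
#' @param config A \code{\link{fed_config}}.
#' @return Logical.
#' @export
is_static_fire <- function(farea, npix, config = fed_config()) {
  if (farea <= 0) return(FALSE)
  farea < config$static_area_km2 && npix / farea > config$static_density
}

#' Refresh scalar fire properties
#'
#' Recomputes the property block of a fire object from its current hull,
#' fireline and pixel sets: area (km2), perimeter (km), centroid (lon/lat),
#' pixel density (pixels per km2), mean FRP of the pixels newly detected at
#' the current step (NA when none), dominant land cover, fire type, active
#' fire line length (km) and duration (days). The ignition-time fuel
#' moisture \code{stFM1000} is sampled once, at the ignition centroid, and
#' kept thereafter.
#'
#' @param fire A fire object (see \code{\link{allfires_init}}).
#' @param lct_grid Land-cover \code{\link{fed_raster}} or NULL.
#' @param fm_field Fuel-moisture \code{\link{fed_raster}} or NULL.
#' @param config A \code{\link{fed_config}}.
#' @return The fire object with updated \code{properties} and \code{ftype}.
#' @export
refresh_properties <- function(fire, lct_grid = NULL, fm_field = NULL,
                               config = fed_config()) {
  farea <- fire$hull$area / 1e6
  ctr <- fg_centroid(fire$hull$geom)
  lonlat <- fed_unproject(ctr[1], ctr[2], config$proj)
  npix <- nrow(fire$pixels)
  newfrp <- fire$pixels$frp[fire$pixels$new]
  p <- list(
    farea = farea,
    fperim = fire$hull$perim / 1e3,
    centroid_lon = unname(lonlat[1, 1]), centroid_lat = unname(lonlat[1, 2]),
    pixden = if (farea > 0) npix / farea else NA_real_,
    meanFRP = if (length(newfrp)) mean(newfrp) else NA_real_,
    flinelen = if (is.null(fire$fline)) 0 else fire$fline$length / 1e3,
    duration = step_diff_days(fire$t_ed, fire$t_st),
    n_pixels = npix,
    n_newpixels = sum(fire$pixels$new)
  )
  # ignition fuel moisture: sampled once at the ignition-pixel centroid
  if (is.null(fire$properties$stFM1000) ||
      is.na(fire$properties$stFM1000)) {
    ign <- fire$pixels[fire$pixels$ign, , drop = FALSE]
    p$stFM1000 <- if (!is.null(fm_field) && nrow(ign) > 0)
      unname(raster_sample(fm_field,
                           matrix(c(mean(ign$x), mean(ign$y)), ncol = 2)))
    else NA_real_
  } else {
    p$stFM1000 <- fire$properties$stFM1000
  }
  if (!is.null(lct_grid)) {
    p$LCTmax <- dominant_landcover(fire$hull, lct_grid)
    fire$ftype <- tryCatch(
      classify_fire_type(p$LCTmax, p$stFM1000, config),
      error = function(e) NA_character_)
  } else {
    p$LCTmax <- fire$properties$LCTmax %||% NA_character_
    fire$ftype <- fire$ftype %||% NA_character_
  }
  fire$properties <- p
  fire
}

`%||%` <- function(a, b) if (is.null(a)) b else a
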