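# The four-layer data suite: restartable state serialization, half-daily
# snapshots, large-fire time series and season summaries.
#
# The state file is an explicit JSON schema written at full floating-point
# precision, so that a run resumed from a checkpoint is bit-identical to an
# uninterrupted run. Snapshot/large-fire products are GeoJSON feature
# collections (perimeter / fireline / newfirepix layers, WGS84);
# summaries are CSV tables. File-name stems follow the YYYYMMDDAP pattern.

STATE_FORMAT_VERSION <- 1L

step_or_null <- function(x) if (is.null(x)) NULL else unclass(x)

# Coordinate matrices are serialized as parallel x/y arrays: unambiguous
# to re-read whatever the simplification settings.
mat_to_xy <- function(m) list(x = m[, 1], y = m[, 2])

xy_to_mat <- function(l) {
  m <- cbind(as.numeric(unlist(l$x)), as.numeric(unlist(l$y)))
  colnames(m) <- c("x", "y")
  m
}

hull_to_list <- function(h) {
  if (is.null(h)) return(NULL)
  list(rings = lapply(h$geom$rings, mat_to_xy),
       area = h$area, perim = h$perim, npix = h$npix, method = h$method)
}

hull_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  structure(list(geom = fgeom(lapply(l$rings, xy_to_mat)),
                 area = l$area, perim = l$perim,
                 npix = l$npix, method = l$method), class = "fed_hull")
}

fline_to_list <- function(fl) {
  if (is.null(fl)) return(NULL)
  list(parts = lapply(fl$parts, mat_to_xy), closed = fl$closed,
       length = fl$length)
}

fline_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  structure(list(parts = lapply(l$parts, xy_to_mat),
                 closed = as.logical(unlist(l$closed)),
                 length = l$length), class = "fed_fline")
}

# Canonical storage types of the fire property block, so that JSON nulls
# come back as typed NAs.
canonical_properties <- function(pr) {
  num <- c("farea", "fperim", "centroid_lon", "centroid_lat", "pixden",
           "meanFRP", "flinelen", "duration", "stFM1000")
  int <- c("n_pixels", "n_newpixels")
  chr <- c("LCTmax")
  out <- lapply(names(pr), function(nm) {
    v <- pr[[nm]]
    if (is.null(v)) v <- NA
    if (nm %in% num) as.numeric(v)
    else if (nm %in% int) as.integer(v)
    else if (nm %in% chr) as.character(v)
    else v
  })
  names(out) <- names(pr)
  out
}

#' Save and load tracker state
#'
#' Lossless JSON round-trip of a \code{fed_allfires} state: the loaded
#' state is identical to the saved one, and a run resumed from a saved
#' checkpoint produces the same downstream products as an uninterrupted
#' run.
#'
#' @param state A \code{fed_allfires}.
#' @param path File path (conventionally \code{YYYYMMDDAP.json}).
#' @return \code{save_state} returns \code{path} invisibly;
#'   \code{load_state} returns the \code{fed_allfires}.
#' @export
save_state <- function(state, path) {
  fires <- lapply(state$fires, function(f) {
    list(id = f$id, pixels = as.list(f$pixels),
         t_st = unclass(f$t_st), t_ed = unclass(f$t_ed),
         invalid = f$invalid, isactive = f$isactive,
         t_inactive = f$t_inactive,
         hull = hull_to_list(f$hull), fline = fline_to_list(f$fline),
         ftype = f$ftype, properties = f$properties)
  })
  obj <- list(
    format = "fed_allfires", version = STATE_FORMAT_VERSION,
    t = step_or_null(state$t),
    heritages = list(source = as.integer(state$heritages[, 1]),
                     target = as.integer(state$heritages[, 2])),
    fids_expanded = state$fids_expanded, fids_new = state$fids_new,
    fids_merged = state$fids_merged, fids_invalid = state$fids_invalid,
    config = unclass(state$config),
    fires = fires
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              null = "null", na = "null"),
             path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(readLines(path, warn = FALSE),
                       simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = TRUE),
    error = function(e) stop("load_state: cannot parse state file: ",
                             conditionMessage(e)))
  if (is.null(obj$format) || obj$format != "fed_allfires")
    stop("load_state: not a tracker state file")
  cfg <- obj$config
  cfg$mode <- cfg$mode[1]
  config <- do.call(fed_config, cfg[names(cfg) %in% names(formals(fed_config))])
  state <- allfires_init(config)
  state$t <- if (is.null(obj$t)) NULL else step_from_index(obj$t)
  her <- matrix(integer(0), ncol = 2,
                dimnames = list(NULL, c("source", "target")))
  if (length(obj$heritages$source))
    her <- cbind(source = as.integer(obj$heritages$source),
                 target = as.integer(obj$heritages$target))
  state$heritages <- her
  state$fids_expanded <- as.integer(unlist(obj$fids_expanded))
  state$fids_new <- as.integer(unlist(obj$fids_new))
  state$fids_merged <- as.integer(unlist(obj$fids_merged))
  state$fids_invalid <- as.integer(unlist(obj$fids_invalid))
  state$fires <- lapply(obj$fires, function(l) {
    px <- l$pixels
    pixels <- if (length(px$x) == 0) empty_pixels() else
      data.frame(x = px$x, y = px$y, lon = px$lon, lat = px$lat,
                 frp = px$frp, t = as.integer(px$t),
                 origin = as.integer(px$origin),
                 new = as.logical(px$new), ign = as.logical(px$ign))
    pr <- l$properties
    if (length(pr)) pr <- canonical_properties(pr)
    list(id = as.integer(l$id), pixels = pixels,
         t_st = step_from_index(l$t_st), t_ed = step_from_index(l$t_ed),
         invalid = l$invalid, isactive = l$isactive,
         t_inactive = as.numeric(l$t_inactive),
         hull = hull_from_list(l$hull), fline = fline_from_list(l$fline),
         ftype = if (is.null(l$ftype)) NA_character_ else l$ftype,
         properties = pr)
  })
  state
}

fire_property_row <- function(f) {
  p <- f$properties
  list(fid = f$id,
       t_st = format(f$t_st), t_ed = format(f$t_ed),
       duration = p$duration %||% NA_real_,
       ftype = f$ftype,
       LCTmax = p$LCTmax %||% NA_character_,
       stFM1000 = p$stFM1000 %||% NA_real_,
       farea = p$farea %||% NA_real_,
       fperim = p$fperim %||% NA_real_,
       flinelen = p$flinelen %||% NA_real_,
       pixden = p$pixden %||% NA_real_,
       meanFRP = p$meanFRP %||% NA_real_,
       n_pixels = p$n_pixels %||% nrow(f$pixels),
       n_newpixels = p$n_newpixels %||% sum(f$pixels$new),
       isactive = f$isactive,
       t_inactive = f$t_inactive,
       centroid_lon = p$centroid_lon %||% NA_real_,
       centroid_lat = p$centroid_lat %||% NA_real_)
}

project_to_lonlat <- function(g, proj) {
  fg_transform(g, function(m) fed_unproject(m[, 1], m[, 2], proj))
}

fline_to_lonlat <- function(fl, proj) {
  structure(list(
    parts = lapply(fl$parts, function(m) {
      out <- fed_unproject(m[, 1], m[, 2], proj)
      colnames(out) <- c("x", "y"); out
    }),
    closed = fl$closed, length = fl$length), class = "fed_fline")
}

#' Write a half-daily snapshot
#'
#' Writes the three snapshot layers for the current state as GeoJSON
#' feature collections named \code{<stem>_perimeter.geojson},
#' \code{<stem>_fireline.geojson} and \code{<stem>_newfirepix.geojson}
#' where the stem is the formatted step (\code{YYYYMMDDAP}). Only valid
#' fires are included; fires with an empty fireline are absent from the
#' fireline layer.
#'
#' @param state A \code{fed_allfires} with a current step.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_snapshot <- function(state, dir) {
  if (is.null(state$t)) stop("write_snapshot: state has no current step")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- format(state$t)
  proj <- state$config$proj
  per <- list(); fl <- list(); np <- list()
  for (f in state$fires) {
    if (f$invalid || is.null(f$hull)) next
    props <- fire_property_row(f)
    per[[length(per) + 1]] <- list(
      geometry = project_to_lonlat(f$hull$geom, proj), properties = props)
    if (!is.null(f$fline) && length(f$fline$parts) > 0)
      fl[[length(fl) + 1]] <- list(
        geometry = fline_to_lonlat(f$fline, proj),
        properties = list(fid = f$id, flinelen = props$flinelen))
    newpix <- f$pixels[f$pixels$new, , drop = FALSE]
    if (nrow(newpix) > 0)
      np[[length(np) + 1]] <- list(
        geometry = cbind(newpix$lon, newpix$lat),
        properties = list(fid = f$id, n = nrow(newpix),
                          meanFRP = props$meanFRP))
  }
  paths <- c(
    perimeter = file.path(dir, paste0(stem, "_perimeter.geojson")),
    fireline = file.path(dir, paste0(stem, "_fireline.geojson")),
    newfirepix = file.path(dir, paste0(stem, "_newfirepix.geojson")))
  write_geojson(per, paths["perimeter"])
  write_geojson(fl, paths["fireline"])
  write_geojson(np, paths["newfirepix"])
  invisible(paths)
}

large_fire_ids <- function(state, threshold = state$config$large_fire_km2) {
  ids <- integer(0)
  for (f in state$fires) {
    if (f$invalid || is.null(f$hull)) next
    if (f$hull$area / 1e6 > threshold) ids <- c(ids, f$id)
  }
  ids
}

#' Write the large-fire time series
#'
#' For every fire whose final area exceeds the threshold (4 km2 by
#' default), emits the per-step perimeter, fireline and new-pixel features
#' from ignition to the last step with activity, as
#' \code{LargeFires_<year>_perimeter.geojson} (etc.) in \code{dir}.
#'
#' @param history Named list of \code{fed_allfires} states, one per step
#'   (as returned by \code{track_records(keep_history = TRUE)}).
#' @param dir Output directory.
#' @param year Year label used in the file names; defaults to the year of
#'   the last step.
#' @param threshold Area threshold in km2.
#' @return Named character vector of file paths, invisibly.
#' @export
write_largefire_series <- function(history, dir, year = NULL,
                                   threshold = NULL) {
  stopifnot(length(history) > 0)
  final <- history[[length(history)]]
  if (is.null(threshold)) threshold <- final$config$large_fire_km2
  if (is.null(year)) year <- format(step_date(final$t), "%Y")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- large_fire_ids(final, threshold)
  proj <- final$config$proj
  per <- list(); fl <- list(); np <- list()
  for (st in history) {
    stem <- format(st$t)
    for (id in ids) {
      if (id > length(st$fires)) next
      f <- st$fires[[id]]
      if (is.null(f) || f$invalid || is.null(f$hull)) next
      props <- c(list(t = stem), fire_property_row(f))
      per[[length(per) + 1]] <- list(
        geometry = project_to_lonlat(f$hull$geom, proj), properties = props)
      if (!is.null(f$fline) && length(f$fline$parts) > 0)
        fl[[length(fl) + 1]] <- list(
          geometry = fline_to_lonlat(f$fline, proj),
          properties = list(t = stem, fid = f$id))
      newpix <- f$pixels[f$pixels$new, , drop = FALSE]
      if (nrow(newpix) > 0)
        np[[length(np) + 1]] <- list(
          geometry = cbind(newpix$lon, newpix$lat),
          properties = list(t = stem, fid = f$id, n = nrow(newpix)))
    }
  }
  paths <- c(
    perimeter = file.path(dir, sprintf("LargeFires_%s_perimeter.geojson", year)),
    fireline = file.path(dir, sprintf("LargeFires_%s_fireline.geojson", year)),
    newfirepix = file.path(dir, sprintf("LargeFires_%s_newfirepix.geojson", year)))
  write_geojson(per, paths["perimeter"])
  write_geojson(fl, paths["fireline"])
  write_geojson(np, paths["newfirepix"])
  invisible(paths)
}

#' Per-step regional summary of a state
#'
#' Aggregates the valid fires of one state into the regional statistics
#' row used by the season summary (fire count, active count, total area,
#' total fireline length, new-pixel count).
#'
#' @param state A \code{fed_allfires}.
#' @return One-row data.frame.
#' @export
summarize_state <- function(state) {
  n_fires <- 0L; n_active <- 0L
  farea <- 0; flen <- 0; npix <- 0L
  for (f in state$fires) {
    if (f$invalid || is.null(f$hull)) next
    n_fires <- n_fires + 1L
    if (f$isactive) n_active <- n_active + 1L
    farea <- farea + f$hull$area / 1e6
    if (!is.null(f$fline)) flen <- flen + f$fline$length / 1e3
    npix <- npix + sum(f$pixels$new)
  }
  data.frame(t = format(state$t), n_fires = n_fires, n_active = n_active,
             total_farea_km2 = farea, total_flinelen_km = flen,
             n_newpixels = npix, stringsAsFactors = FALSE)
}

#' Write the season summary product
#'
#' Writes the regional half-daily time series
#' (\code{fsummary_<year>1231PM.csv}), the merge-heritage list
#' (\code{Flist_heritage_<year>.csv}) and the large-fire id list
#' (\code{Flist_large_<year>.csv}).
#'
#' @inheritParams write_largefire_series
#' @return Named character vector of file paths, invisibly.
#' @export
write_summary <- function(history, dir, year = NULL, threshold = NULL) {
  stopifnot(length(history) > 0)
  final <- history[[length(history)]]
  if (is.null(threshold)) threshold <- final$config$large_fire_km2
  if (is.null(year)) year <- format(step_date(final$t), "%Y")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- do.call(rbind, lapply(history, summarize_state))
  her <- as.data.frame(final$heritages)
  large <- data.frame(fid = large_fire_ids(final, threshold))
  paths <- c(
    series = file.path(dir, sprintf("fsummary_%s1231PM.csv", year)),
    heritage = file.path(dir, sprintf("Flist_heritage_%s.csv", year)),
    large = file.path(dir, sprintf("Flist_large_%s.csv", year)))
  utils::write.csv(series, paths["series"], row.names = FALSE)
  utils::write.csv(her, paths["heritage"], row.names = FALSE)
  utils::write.csv(large, paths["large"], row.names = FALSE)
  invisible(paths)
}
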