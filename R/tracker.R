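# The object lifecycle engine: cluster new pixels, assign clusters to
# fires, create/expand/merge/expire fire objects at each half-daily step.
#
# A fire object is a list with the pixel table (projected and geographic
# coordinates, FRP, detection step, origin id, new/ignition flags),
# lifecycle fields (t_st, t_ed, invalid, isactive, t_inactive), the hull
# and fireline geometries, the fire type and the scalar property block.
# The allfires state holds the id-indexed fire list, the merge heritage,
# and the per-step changed-id lists.

#' Initialise an empty allfires state
#'
#' @param config A \code{\link{fed_config}}.
#' @return An object of class \code{fed_allfires}.
#' @export
allfires_init <- function(config = fed_config()) {
  structure(list(
    fires = list(), t = NULL,
    heritages = matrix(integer(0), ncol = 2,
                       dimnames = list(NULL, c("source", "target"))),
    fids_expanded = integer(0), fids_new = integer(0),
    fids_merged = integer(0), fids_invalid = integer(0),
    config = config
  ), class = "fed_allfires")
}

#' @export
print.fed_allfires <- function(x, ...) {
  nv <- sum(vapply(x$fires, function(f) !f$invalid, TRUE))
  cat(sprintf("<fed_allfires> step %s: %d fire(s) (%d valid), %d merge(s)\n",
              if (is.null(x$t)) "-" else format(x$t),
              length(x$fires), nv, nrow(x$heritages)))
  invisible(x)
}

empty_pixels <- function() {
  data.frame(x = numeric(0), y = numeric(0), lon = numeric(0),
             lat = numeric(0), frp = numeric(0), t = integer(0),
             origin = integer(0), new = logical(0), ign = logical(0))
}

new_fire <- function(id, pixels, step) {
  list(id = id, pixels = pixels, t_st = step, t_ed = step,
       invalid = FALSE, isactive = TRUE, t_inactive = 0,
       hull = NULL, fline = NULL, ftype = NA_character_,
       properties = list())
}

#' Cluster same-step fire pixels by proximity
#'
#' Single-linkage connected components: two pixels belong to the same
#' cluster when they are joined by a chain of links no longer than the
#' linkage distance. Cluster labels are ordered by each cluster's first
#' pixel in record order, so ids issued from them are reproducible.
#'
#' @param pts 2-column matrix of projected pixel coordinates (metres).
#' @param linkage Linkage distance in metres.
#' @return Integer vector of cluster labels (1-based, ordered by first
#'   occurrence).
#' @export
cluster_pixels <- function(pts, linkage) {
  pts <- coerce_pts(pts)
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::dist(pts), method = "single")
  lab <- stats::cutree(hc, h = linkage)
  # relabel in order of first appearance
  first <- match(unique(lab), lab)
  ord <- order(first)
  match(lab, unique(lab)[ord])
}

#' Nearest active fire for a cluster
#'
#' Among valid, active fires, finds the one whose perimeter is closest to
#' the cluster pixels, provided that distance is within the fire's
#' type-dependent extended-area buffer (5 km for forest fires, 1 km
#' otherwise). Ties go to the lower fire id.
#'
#' @param cluster_pts 2-column matrix of projected cluster pixel
#'   coordinates.
#' @param state A \code{fed_allfires}.
#' @return List with \code{id} (integer or NA) and \code{dist} (metres).
#' @export
nearest_active_fire <- function(cluster_pts, state) {
  cluster_pts <- coerce_pts(cluster_pts)
  best_id <- NA_integer_; best_d <- Inf
  for (f in state$fires) {
    if (f$invalid || !f$isactive || is.null(f$hull)) next
    d <- min(fg_dist(f$hull$geom, cluster_pts))
    if (d <= type_buffer(f$ftype, state$config) &&
        (d < best_d - 1e-9 ||
         (abs(d - best_d) <= 1e-9 && !is.na(best_id) && f$id < best_id))) {
      best_d <- d; best_id <- f$id
    }
  }
  list(id = best_id, dist = best_d)
}

update_fire_geometry <- function(fire, config) {
  fire$hull <- fire_hull(as.matrix(fire$pixels[, c("x", "y")]),
                         alpha = config$alpha,
                         buffer = config$pixel_buffer,
                         arc_segments = config$arc_segments,
                         circle_segments = config$circle_segments)
  newpts <- as.matrix(fire$pixels[fire$pixels$new, c("x", "y"),
                                  drop = FALSE])
  fire$fline <- active_fireline(fire$hull, newpts, config$fline_radius)
  fire
}

#' Assign clusters to fires
#'
#' Each cluster is appended to the nearest active fire whose extended area
#' it overlaps, or becomes a new fire object with a fresh sequential id.
#' Pixel origin ids are set at assignment and never change.
#'
#' @param state A \code{fed_allfires} whose \code{t} is the current step.
#' @param clusters List of pixel tables (one per cluster), all at the
#'   current step.
#' @return The updated state (geometry of changed fires not yet refreshed;
#'   \code{\link{advance}} handles that).
#' @export
apply_clusters <- function(state, clusters) {
  for (cl in clusters) {
    hit <- nearest_active_fire(as.matrix(cl[, c("x", "y")]), state)
    if (!is.na(hit$id)) {
      f <- state$fires[[hit$id]]
      cl$origin <- f$id
      cl$new <- TRUE
      cl$ign <- FALSE
      f$pixels <- rbind(f$pixels, cl)
      rownames(f$pixels) <- NULL
      f$t_ed <- state$t
      state$fires[[hit$id]] <- f
      if (!(hit$id %in% state$fids_new))
        state$fids_expanded <- union(state$fids_expanded, hit$id)
    } else {
      id <- length(state$fires) + 1L
      cl$origin <- id
      cl$new <- TRUE
      cl$ign <- TRUE
      state$fires[[id]] <- new_fire(id, cl, state$t)
      state$fids_new <- c(state$fids_new, id)
    }
  }
  state
}

#' Merge grown fires
#'
#' Repeats until fixpoint: whenever a fire changed at the current step lies
#' within another valid active fire's extended area, all pixels of the
#' higher-id fire (the source, with the later start) move to the lower-id
#' fire (the target), the source is flagged invalid and the (source,
#' target) pair is appended to the heritage list. Scan order is ascending
#' source id with a restart after every merge, so transitive chains resolve
#' deterministically.
#'
#' @param state A \code{fed_allfires} with up-to-date hulls.
#' @return The updated state.
#' @export
merge_grown_fires <- function(state) {
  cfg <- state$config
  repeat {
    changed <- sort(unique(c(state$fids_expanded, state$fids_new,
                             state$fids_merged)))
    merged_any <- FALSE
    for (ida in changed) {
      fa <- state$fires[[ida]]
      if (fa$invalid || !fa$isactive || is.null(fa$hull)) next
      for (fb in state$fires) {
        if (fb$id == ida || fb$invalid || !fb$isactive ||
            is.null(fb$hull)) next
        d <- fg_geom_dist(fa$hull$geom, fb$hull$geom)
        if (d <= type_buffer(fb$ftype, cfg)) {
          src_id <- max(ida, fb$id); tgt_id <- min(ida, fb$id)
          src <- state$fires[[src_id]]; tgt <- state$fires[[tgt_id]]
          moved <- src$pixels
          moved$ign <- FALSE
          tgt$pixels <- rbind(tgt$pixels, moved)
          rownames(tgt$pixels) <- NULL
          tgt$t_st <- step_from_index(min(unclass(tgt$t_st),
                                          unclass(src$t_st)))
          tgt$t_ed <- step_from_index(max(unclass(tgt$t_ed),
                                          unclass(src$t_ed)))
          src$pixels <- empty_pixels()
          src$invalid <- TRUE
          src$isactive <- FALSE
          tgt <- update_fire_geometry(tgt, cfg)
          state$fires[[src_id]] <- src
          state$fires[[tgt_id]] <- tgt
          state$heritages <- rbind(state$heritages,
                                   c(source = src_id, target = tgt_id))
          state$fids_merged <- union(state$fids_merged, tgt_id)
          state$fids_invalid <- union(state$fids_invalid, src_id)
          state$fids_expanded <- setdiff(state$fids_expanded, src_id)
          state$fids_new <- setdiff(state$fids_new, src_id)
          state$fids_merged <- setdiff(state$fids_merged, src_id)
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  state
}

#' Update fire activity status
#'
#' A valid fire stays active while its last detection is at most 5 days
#' (10 half-daily steps) old; once inactive it never reactivates (later
#' nearby clusters start new fires).
#'
#' @param state A \code{fed_allfires}.
#' @return The updated state.
#' @export
update_activity <- function(state) {
  lim <- 2L * state$config$inactive_days
  for (i in seq_along(state$fires)) {
    f <- state$fires[[i]]
    if (f$invalid) { f$isactive <- FALSE; state$fires[[i]] <- f; next }
    f$t_inactive <- step_diff_days(state$t, f$t_ed)
    f$isactive <- (unclass(state$t) - unclass(f$t_ed)) <= lim
    state$fires[[i]] <- f
  }
  state
}

#' Advance the tracker by one half-daily step
#'
#' Orchestrates one step: project the batch, cluster pixels, assign
#' clusters to fires, rebuild hulls and firelines of changed fires, merge
#' grown fires, apply the static-source filter, update activity and
#' refresh fire properties. The changed-id lists reflect exactly this
#' step's changes.
#'
#' @param state A \code{fed_allfires}; its step must precede \code{step} by
#'   exactly one half-day (or be NULL for the first step).
#' @param batch Filtered record table for this step (may be empty).
#' @param step The \code{\link{fed_step}} being processed.
#' @param lct_grid,fm_field Optional \code{\link{fed_raster}} grids for
#'   land-cover classification and ignition fuel moisture.
#' @return The updated \code{fed_allfires}.
#' @export
advance <- function(state, batch, step, lct_grid = NULL, fm_field = NULL) {
  cfg <- state$config
  if (!is.null(state$t) && unclass(step) != unclass(state$t) + 1L)
    stop("advance: step ", format(step), " does not follow state step ",
         format(state$t))
  state$t <- step
  state$fids_expanded <- integer(0)
  state$fids_new <- integer(0)
  state$fids_merged <- integer(0)
  state$fids_invalid <- integer(0)

  # previous step's new pixels are no longer new
  for (i in seq_along(state$fires)) {
    f <- state$fires[[i]]
    if (any(f$pixels$new)) {
      f$pixels$new <- FALSE
      f$fline <- active_fireline(f$hull, matrix(0, 0, 2),
                                 cfg$fline_radius)
      f$properties$flinelen <- 0
      f$properties$meanFRP <- NA_real_
      f$properties$n_newpixels <- 0L
      state$fires[[i]] <- f
    }
  }

  if (nrow(batch) > 0) {
    xy <- fed_project(batch$lon, batch$lat, cfg$proj)
    px <- data.frame(x = xy[, 1], y = xy[, 2], lon = batch$lon,
                     lat = batch$lat, frp = batch$frp,
                     t = rep(unclass(step), nrow(batch)),
                     origin = NA_integer_, new = TRUE, ign = FALSE)
    lab <- cluster_pixels(cbind(px$x, px$y), cfg$linkage)
    clusters <- lapply(seq_len(max(lab)), function(k)
      px[lab == k, , drop = FALSE])
    state <- apply_clusters(state, clusters)
    for (id in c(state$fids_expanded, state$fids_new))
      state$fires[[id]] <- update_fire_geometry(state$fires[[id]], cfg)
    state <- merge_grown_fires(state)
  }

  # static-source filter on fires changed this step
  if (cfg$static_filter) {
    for (id in sort(unique(c(state$fids_expanded, state$fids_new,
                             state$fids_merged)))) {
      f <- state$fires[[id]]
      if (f$invalid || is.null(f$hull)) next
      if (is_static_fire(f$hull$area / 1e6, nrow(f$pixels), cfg)) {
        f$invalid <- TRUE
        f$isactive <- FALSE
        state$fires[[id]] <- f
        state$fids_invalid <- union(state$fids_invalid, id)
      }
    }
  }

  state <- update_activity(state)

  for (id in sort(unique(c(state$fids_expanded, state$fids_new,
                           state$fids_merged)))) {
    f <- state$fires[[id]]
    if (f$invalid) next
    state$fires[[id]] <- refresh_properties(f, lct_grid, fm_field, cfg)
  }
  state
}

#' Run the tracker over a step sequence
#'
#' Convenience loop over \code{\link{advance}}: filters and partitions the
#' records, advances the state through every step, and optionally collects
#' the state history.
#'
#' @param records Record table (see \code{\link{read_detections}}).
#' @param start,end \code{\link{fed_step}} bounds (inclusive).
#' @param roi Optional region polygon (\code{fgeom}, lon/lat).
#' @param lct_grid,fm_field Optional rasters.
#' @param config A \code{\link{fed_config}}.
#' @param state Optional restart state (resume from \code{state$t + 1}).
#' @param keep_history Logical; if TRUE the returned list contains the
#'   state after every step under \code{$history}.
#' @param quiet Suppress per-step log lines.
#' @return List with \code{state} (final \code{fed_allfires}) and
#'   optionally \code{history}.
#' @export
track_records <- function(records, start, end, roi = NULL,
                          lct_grid = NULL, fm_field = NULL,
                          config = fed_config(), state = NULL,
                          keep_history = FALSE, quiet = TRUE) {
  if (is.null(state)) state <- allfires_init(config)
  config <- state$config
  recs <- filter_records(records, roi = roi, config = config)
  steps <- step_sequence(start, end)
  batches <- partition_records(recs, steps, config)
  history <- if (keep_history) vector("list", length(steps)) else NULL
  for (k in seq_along(steps)) {
    state <- advance(state, batches[[k]], steps[[k]], lct_grid, fm_field)
    if (!quiet)
      message(sprintf("%s: %d px, %d new, %d expanded, %d merged",
                      format(steps[[k]]), nrow(batches[[k]]),
                      length(state$fids_new), length(state$fids_expanded),
                      nrow(state$heritages)))
    if (keep_history) history[[k]] <- state
  }
  if (keep_history) names(history) <- names(batches)
  list(state = state, history = history)
}
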