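# GeoJSON reading and writing via jsonlite. Geometries on disk are WGS84
# lon/lat; the projected metre plane is internal only.

# Apply a coordinate transform function (n x 2 -> n x 2) to all rings.
fg_transform <- function(g, fun) {
  fgeom(lapply(g$rings, function(m) {
    out <- fun(m)
    colnames(out) <- c("x", "y")
    out
  }))
}

# Group signed rings into GeoJSON polygons: each CCW outer ring collects
# the CW holes it contains.
fg_to_polygons <- function(g) {
  areas <- vapply(g$rings, ring_area, 0)
  outers <- which(areas >= 0); holes <- which(areas < 0)
  polys <- lapply(outers, function(i) list(outer = g$rings[[i]],
                                           holes = list()))
  for (h in holes) {
    p <- matrix(g$rings[[h]][1, ], ncol = 2)
    owner <- NA
    best_area <- Inf
    for (k in seq_along(outers)) {
      i <- outers[k]
      if (pts_in_ring(p, g$rings[[i]]) && areas[i] < best_area) {
        owner <- k; best_area <- areas[i]
      }
    }
    if (!is.na(owner))
      polys[[owner]]$holes <- c(polys[[owner]]$holes, list(g$rings[[h]]))
  }
  polys
}

close_ring <- function(m) rbind(m, m[1, , drop = FALSE])

ring_coords <- function(m) {
  m <- close_ring(m)
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

geojson_geometry <- function(geom) {
  if (inherits(geom, "fgeom")) {
    polys <- fg_to_polygons(geom)
    if (length(polys) == 0) return(NULL)
    coords <- lapply(polys, function(p)
      c(list(ring_coords(p$outer)), lapply(p$holes, ring_coords)))
    if (length(coords) == 1)
      list(type = "Polygon", coordinates = coords[[1]])
    else list(type = "MultiPolygon", coordinates = coords)
  } else if (inherits(geom, "fed_fline")) {
    if (length(geom$parts) == 0) return(NULL)
    lines <- lapply(seq_along(geom$parts), function(i) {
      m <- geom$parts[[i]]
      if (geom$closed[i]) m <- close_ring(m)
      lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))
    })
    if (length(lines) == 1)
      list(type = "LineString", coordinates = lines[[1]])
    else list(type = "MultiLineString", coordinates = lines)
  } else if (is.matrix(geom)) {
    if (nrow(geom) == 0) return(NULL)
    pts <- lapply(seq_len(nrow(geom)), function(i) c(geom[i, 1], geom[i, 2]))
    if (length(pts) == 1) list(type = "Point", coordinates = pts[[1]])
    else list(type = "MultiPoint", coordinates = pts)
  } else NULL
}

#' Write a GeoJSON feature collection
#'
#' @param features List of features, each a list with elements
#'   \code{geometry} (an \code{fgeom}, a \code{fed_fline}, or a point
#'   matrix, all in lon/lat) and \code{properties} (named list).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_geojson <- function(features, path) {
  feats <- list()
  for (f in features) {
    gg <- geojson_geometry(f$geometry)
    if (is.null(gg)) next
    props <- lapply(f$properties, function(v)
      if (is.null(v) || length(v) == 0) NA else v)
    feats[[length(feats) + 1]] <-
      list(type = "Feature", properties = props, geometry = gg)
  }
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             path)
  invisible(path)
}

coords_to_rings <- function(coords) {
  lapply(coords, function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-12))
      m <- m[-nrow(m), , drop = FALSE]
    m
  })
}

#' Read a GeoJSON file of polygon features
#'
#' Parses Polygon/MultiPolygon features (Feature, FeatureCollection or a
#' bare geometry) into \code{fgeom} objects with even-odd ring orientation
#' normalised.
#'
#' @param path GeoJSON file path.
#' @return List with \code{geoms} (list of \code{fgeom}) and
#'   \code{properties} (data.frame, one row per feature).
#' @export
read_geojson_polygons <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  feats <- switch(doc$type,
    FeatureCollection = doc$features,
    Feature = list(doc),
    list(list(type = "Feature", properties = list(), geometry = doc)))
  geoms <- list(); props <- list()
  for (f in feats) {
    g <- f$geometry
    rings <- switch(g$type,
      Polygon = coords_to_rings(g$coordinates),
      MultiPolygon = do.call(c, lapply(g$coordinates, coords_to_rings)),
      NULL)
    if (is.null(rings)) next
    geoms[[length(geoms) + 1]] <- orient_fgeom(fgeom(rings))
    p <- f$properties
    props[[length(props) + 1]] <-
      if (length(p)) as.data.frame(lapply(p, function(v)
        if (is.null(v)) NA else v), stringsAsFactors = FALSE)
      else data.frame(row.names = 1)
  }
  properties <- if (length(props)) do.call(rbind_fill, props) else NULL
  list(geoms = geoms, properties = properties)
}

# rbind data.frames with unequal columns (fills NA).
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols, drop = FALSE]
  }))
}
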