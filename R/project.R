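#' Equal-area projection of geographic coordinates
#'
#' Forward and inverse spherical Albers equal-area conic projection. All
#' metre-valued thresholds in the tracker (alpha radius, buffers, linkage
#' distances) and all km2 areas are evaluated on this plane, so a single
#' equal-area projection is used for the whole region. The default
#' parameters (standard parallels 34 and 40.5, central meridian -120)
#' follow the conventional Albers setup for California; override them in
#' \code{\link{fed_config}} for other regions.
#'
#' @param lon,lat Numeric vectors of geographic coordinates (degrees,
#'   WGS84-style lon/lat).
#' @param proj List with elements \code{lon0}, \code{lat0} (projection
#'   origin), \code{lat1}, \code{lat2} (standard parallels, degrees) and
#'   \code{R} (sphere radius, metres).
#' @return \code{fed_project} returns a 2-column matrix (x, y in metres);
#'   \code{fed_unproject} a 2-column matrix (lon, lat in degrees).
#' @examples
#' p <- fed_project(-121, 38)
#' fed_unproject(p[, 1], p[, 2])
#' @export
fed_project <- function(lon, lat, proj = fed_config()$proj) {
  stopifnot(all(abs(lat) <= 90), all(abs(lon) <= 180))
  d2r <- pi / 180
  phi1 <- proj$lat1 * d2r; phi2 <- proj$lat2 * d2r
  n <- (sin(phi1) + sin(phi2)) / 2
  C <- cos(phi1)^2 + 2 * n * sin(phi1)
  rho0 <- proj$R / n * sqrt(C - 2 * n * sin(proj$lat0 * d2r))
  rho <- proj$R / n * sqrt(C - 2 * n * sin(lat * d2r))
  theta <- n * (lon - proj$lon0) * d2r
  cbind(x = rho * sin(theta), y = rho0 - rho * cos(theta))
}

#' @rdname fed_project
#' @param x,y Numeric vectors of projected coordinates in metres.
#' @export
fed_unproject <- function(x, y, proj = fed_config()$proj) {
  d2r <- pi / 180
  phi1 <- proj$lat1 * d2r; phi2 <- proj$lat2 * d2r
  n <- (sin(phi1) + sin(phi2)) / 2
  C <- cos(phi1)^2 + 2 * n * sin(phi1)
  rho0 <- proj$R / n * sqrt(C - 2 * n * sin(proj$lat0 * d2r))
  rho <- sqrt(x^2 + (rho0 - y)^2)
  theta <- atan2(x, rho0 - y)
  s <- (C - (rho * n / proj$R)^2) / (2 * n)
  s <- pmin(1, pmax(-1, s))
  cbind(lon = proj$lon0 + theta / (n * d2r), lat = asin(s) / d2r)
}
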