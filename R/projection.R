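#' Polar Lambert azimuthal equal-area projection
#'
#' Forward projection of WGS84 longitude/latitude (degrees) to planar
#' metres under the north-polar aspect of the Lambert azimuthal equal-area
#' projection, with a configurable central meridian (default 45 degrees
#' East). A spherical earth of authalic radius is used, which keeps the
#' projection exactly invertible and equal-area on the sphere; at the
#' sub-kilometre scales used here the difference from the ellipsoidal
#' solution is irrelevant for distances measured between projected points.
#'
#' @param lon,lat numeric vectors of equal length, degrees.
#' @param lon0 central meridian in degrees (default 45).
#' @param R earth radius in metres (default authalic radius 6371007.181).
#' @return a two-column matrix with columns `x`, `y` in metres.
#' @seealso [laea_unproject()]
#' @export
laea_project <- function(lon, lat, lon0 = 45, R = 6371007.181) {
  if (length(lon) != length(lat)) stop("lon and lat must have equal length")
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates")
  if (any(abs(lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 180)) stop("longitude outside [-180, 180]")
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  # north-polar aspect: rho = 2 R sin((pi/2 - phi)/2)
  rho <- 2 * R * sin((pi / 2 - phi) / 2)
  cbind(x = rho * sin(lam), y = -rho * cos(lam))
}

#' Inverse polar Lambert azimuthal equal-area projection
#'
#' @param x,y numeric vectors, metres (as produced by [laea_project()]).
#' @inheritParams laea_project
#' @return a two-column matrix with columns `lon`, `lat` in degrees.
#' @export
laea_unproject <- function(x, y, lon0 = 45, R = 6371007.181) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  rho <- sqrt(x^2 + y^2)
  s <- pmin(1, rho / (2 * R))
  lat <- 90 - 2 * asin(s) * 180 / pi
  lon <- ifelse(rho < .Machine$double.eps, lon0,
                lon0 + atan2(x, -y) * 180 / pi)
  lon <- ((lon + 180) %% 360) - 180
  cbind(lon = lon, lat = lat)
}
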