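#' Great-circle distance on a spherical Earth
#'
#' Haversine distance between pairs of lon/lat points, with the Earth radius
#' fixed at 6371.0 km. Inputs are recycled, so one argument may be a single
#' point and the other a matrix of points.
#'
#' @param p1,p2 A numeric vector `c(lon, lat)` in decimal degrees, or a
#'   two-column matrix / data frame with columns `lon` and `lat`.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(c(0, 0), c(1, 0))   # one degree of longitude at the equator
#' @export
haversine_km <- function(p1, p2) {
  p1 <- as_lonlat(p1)
  p2 <- as_lonlat(p2)
  n <- if (nrow(p1) == 0L || nrow(p2) == 0L) 0L else max(nrow(p1), nrow(p2))
  i1 <- rep_len(seq_len(nrow(p1)), n)
  i2 <- rep_len(seq_len(nrow(p2)), n)
  hav_km(p1[i1, 1], p1[i1, 2], p2[i2, 1], p2[i2, 2])
}

# raw vectorised haversine on degree inputs
hav_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * 6371.0 * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing
#'
#' Compass bearing (degrees clockwise from north, in `[0, 360)`) of the
#' great-circle path from the first point towards the second.
#'
#' @inheritParams haversine_km
#' @return Numeric vector of bearings in degrees.
#' @export
bearing_deg <- function(p1, p2) {
  p1 <- as_lonlat(p1)
  p2 <- as_lonlat(p2)
  n <- if (nrow(p1) == 0L || nrow(p2) == 0L) 0L else max(nrow(p1), nrow(p2))
  i1 <- rep_len(seq_len(nrow(p1)), n)
  i2 <- rep_len(seq_len(nrow(p2)), n)
  r <- pi / 180
  lon1 <- p1[i1, 1] * r; lat1 <- p1[i1, 2] * r
  lon2 <- p2[i2, 1] * r; lat2 <- p2[i2, 2] * r
  dlon <- lon2 - lon1
  th <- atan2(
    sin(dlon) * cos(lat2),
    cos(lat1) * sin(lat2) - sin(lat1) * cos(lat2) * cos(dlon)
  )
  (th / r) %% 360
}

# coerce a point spec to an n x 2 matrix (lon, lat) and range-check it
as_lonlat <- function(p) {
  if (is.data.frame(p)) {
    if (!all(c("lon", "lat") %in% names(p)))
      stop("data frame points need 'lon' and 'lat' columns")
    p <- cbind(p$lon, p$lat)
  } else if (is.null(dim(p))) {
    if (length(p) != 2L) stop("a point must be c(lon, lat)")
    p <- matrix(p, ncol = 2L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stop("point matrix must have two columns (lon, lat)")
  }
  storage.mode(p) <- "double"
  if (anyNA(p) || any(abs(p[, 1]) > 180) || any(abs(p[, 2]) > 90))
    stop("coordinates out of range: lon in [-180, 180], lat in [-90, 90]")
  p
}

# project lon/lat to azimuthal-equidistant km coordinates about `origin`
# (x east, y north); exact on the sphere: range = great-circle distance,
# direction = initial bearing from the origin
project_aeq <- function(p, origin) {
  p <- as_lonlat(p)
  origin <- as_lonlat(origin)
  d <- haversine_km(origin, p)
  az <- bearing_deg(origin, p) * pi / 180
  cbind(x_km = d * sin(az), y_km = d * cos(az))
}

# inverse of project_aeq: spherical destination point from origin
unproject_aeq <- function(xy, origin) {
  origin <- as_lonlat(origin)
  r <- pi / 180
  lon1 <- origin[1, 1] * r; lat1 <- origin[1, 2] * r
  d <- sqrt(xy[, 1]^2 + xy[, 2]^2) / 6371.0
  az <- atan2(xy[, 1], xy[, 2])
  lat2 <- asin(sin(lat1) * cos(d) + cos(lat1) * sin(d) * cos(az))
  lon2 <- lon1 + atan2(
    sin(az) * sin(d) * cos(lat1),
    cos(d) - sin(lat1) * sin(lat2)
  )
  cbind(lon = ((lon2 / r + 180) %% 360) - 180, lat = lat2 / r)
}
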