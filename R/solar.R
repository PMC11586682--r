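#' Solar elevation angle
#'
#' Geometric solar elevation (degrees above the horizon, no atmospheric
#' refraction) at given times and positions, computed with the NOAA
#' low-accuracy solar ephemeris (Meeus-style truncated series; position
#' accurate to well under 0.2 degrees over recent decades).
#'
#' @param time `POSIXct` times (converted to UTC internally).
#' @param lon,lat Position in decimal degrees; recycled against `time`.
#' @return Numeric vector of elevations in degrees.
#' @export
solar_elevation <- function(time, lon, lat) {
  if (!inherits(time, "POSIXct")) stop("'time' must be POSIXct")
  secs <- as.numeric(time)
  jd <- secs / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  r <- pi / 180

  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e  <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  c  <- sin(m * r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
        sin(2 * m * r) * (0.019993 - 0.000101 * jc) +
        sin(3 * m * r) * 0.000289
  true_long <- l0 + c
  omega <- 125.04 - 1934.136 * jc
  lambda <- true_long - 0.00569 - 0.00478 * sin(omega * r)

  obliq0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- obliq0 + 0.00256 * cos(omega * r)
  decl <- asin(sin(obliq * r) * sin(lambda * r)) / r

  y <- tan(obliq * r / 2)^2
  eqtime <- 4 / r * (y * sin(2 * l0 * r) - 2 * e * sin(m * r) +
    4 * e * y * sin(m * r) * cos(2 * l0 * r) -
    0.5 * y^2 * sin(4 * l0 * r) - 1.25 * e^2 * sin(2 * m * r))

  mins_utc <- (secs %% 86400) / 60
  tst <- (mins_utc + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180

  cosz <- sin(lat * r) * sin(decl * r) +
    cos(lat * r) * cos(decl * r) * cos(ha * r)
  90 - acos(pmin(1, pmax(-1, cosz))) / r
}

#' Remove night-time fixes
#'
#' Retains fixes whose solar elevation at the fix position and time is at or
#' above the civil-twilight limit (-6 degrees by default), dropping the
#' night-time period between the end of civil dusk and the start of civil
#' dawn, when seabirds typically rest on the water. Idempotent: filtering an
#' already-filtered set changes nothing.
#'
#' @param fixes Data frame with columns `timestamp` (`POSIXct`), `lon`, `lat`.
#' @param min_elevation_deg Retention threshold on solar elevation (degrees).
#' @return The subset of `fixes` taken during daylight or civil twilight.
#' @export
filter_daylight <- function(fixes, min_elevation_deg = -6) {
  stopifnot(is.data.frame(fixes),
            all(c("timestamp", "lon", "lat") %in% names(fixes)))
  if (!inherits(fixes$timestamp, "POSIXct"))
    stop("timestamps must be POSIXct (with dates)")
  if (anyNA(fixes$timestamp)) stop("missing timestamps")
  if (nrow(fixes) == 0L) return(fixes)
  elev <- solar_elevation(fixes$timestamp, fixes$lon, fixes$lat)
  fixes[elev >= min_elevation_deg, , drop = FALSE]
}
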