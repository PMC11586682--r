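#' Split GPS fixes into foraging trips around a colony buffer
#'
#' A trip is a maximal run of consecutive fixes (per bird) whose great-circle
#' distance to the colony exceeds `buffer_km`. Fixes inside the buffer —
#' where birds bathe and raft rather than forage — are discarded. A trip is
#' *complete* when it is both preceded and followed by at least one in-buffer
#' fix, i.e. the bird was observed leaving the colony and returning to it;
#' trips truncated by deployment start or logger failure are flagged
#' incomplete and should be excluded from analysis.
#'
#' @param fixes Data frame with columns `bird_id`, `timestamp` (`POSIXct`),
#'   `lon`, `lat`, sorted by time within bird.
#' @param colony Colony position `c(lon, lat)` in decimal degrees.
#' @param buffer_km Colony buffer radius in km (default 2).
#' @return An object of class `cpf_trips`: a list with
#'   \describe{
#'     \item{fixes}{all out-of-buffer fixes with added columns `trip_id`,
#'       `colony_dist_km` and `complete`;}
#'     \item{trips}{one row per trip: `trip_id`, `bird_id`, `n_fixes`,
#'       `start`, `end`, `complete`, `max_dist_km`.}
#'   }
#' @export
split_trips <- function(fixes, colony, buffer_km = 2) {
  stopifnot(is.data.frame(fixes))
  need <- c("bird_id", "timestamp", "lon", "lat")
  if (!all(need %in% names(fixes))) stop("fixes need columns: ",
                                         paste(need, collapse = ", "))
  empty_fix <- cbind(fixes[0, , drop = FALSE],
                     trip_id = character(0), colony_dist_km = numeric(0),
                     complete = logical(0))
  empty_trip <- data.frame(trip_id = character(0), bird_id = character(0),
                           n_fixes = integer(0),
                           start = as.POSIXct(character(0), tz = "UTC"),
                           end = as.POSIXct(character(0), tz = "UTC"),
                           complete = logical(0), max_dist_km = numeric(0))
  if (nrow(fixes) == 0L)
    return(structure(list(fixes = empty_fix, trips = empty_trip),
                     class = "cpf_trips"))

  colony <- as_lonlat(colony)
  out_fix <- list(); out_trip <- list()
  for (b in unique(fixes$bird_id)) {
    fb <- fixes[fixes$bird_id == b, , drop = FALSE]
    if (is.unsorted(as.numeric(fb$timestamp), strictly = TRUE))
      stop("timestamps must be strictly increasing within bird ", b)
    d <- haversine_km(colony, cbind(fb$lon, fb$lat))
    away <- d > buffer_km
    if (!any(away)) next
    r <- rle(away)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- 0L
    for (j in which(r$values)) {
      k <- k + 1L
      i0 <- starts[j]; i1 <- ends[j]
      complete <- i0 > 1L && i1 < nrow(fb)
      tid <- sprintf("%s_T%02d", b, k)
      seg <- fb[i0:i1, , drop = FALSE]
      seg$trip_id <- tid
      seg$colony_dist_km <- d[i0:i1]
      seg$complete <- complete
      out_fix[[tid]] <- seg
      out_trip[[tid]] <- data.frame(
        trip_id = tid, bird_id = b, n_fixes = i1 - i0 + 1L,
        start = seg$timestamp[1], end = seg$timestamp[nrow(seg)],
        complete = complete, max_dist_km = max(seg$colony_dist_km))
    }
  }
  if (length(out_fix) == 0L)
    return(structure(list(fixes = empty_fix, trips = empty_trip),
                     class = "cpf_trips"))
  structure(list(fixes = do.call(rbind, c(out_fix, make.row.names = FALSE)),
                 trips = do.call(rbind, c(out_trip, make.row.names = FALSE))),
            class = "cpf_trips")
}

#' @export
print.cpf_trips <- function(x, ...) {
  cat("cpf_trips:", nrow(x$trips), "trips (",
      sum(x$trips$complete), "complete ),",
      nrow(x$fixes), "out-of-buffer fixes\n")
  invisible(x)
}

#' Assign outbound/inbound legs relative to the distal point
#'
#' The distal point of a trip is the fix with the greatest colony distance
#' (ties broken by the earliest such fix). Fixes at or before the distal
#' point belong to the outbound leg, later fixes to the inbound leg.
#' `distal_signed_km` is the great-circle distance to the distal fix, signed
#' negative on the outbound leg and positive on the inbound leg (0 at the
#' distal fix itself).
#'
#' @param trips A `cpf_trips` object from [split_trips()], or a fix data
#'   frame with `trip_id` and `colony_dist_km` columns.
#' @return The same structure with per-fix columns `leg` (factor
#'   outbound/inbound) and `distal_signed_km`, and (for `cpf_trips` input) a
#'   `distal_index` column on the trip table.
#' @export
annotate_legs <- function(trips) {
  is_obj <- inherits(trips, "cpf_trips")
  fx <- if (is_obj) trips$fixes else trips
  stopifnot(all(c("trip_id", "colony_dist_km", "lon", "lat") %in% names(fx)))
  fx$leg <- factor(NA_character_, levels = c("outbound", "inbound"))
  fx$distal_signed_km <- NA_real_
  distal_idx <- integer(0)
  for (tid in unique(fx$trip_id)) {
    i <- which(fx$trip_id == tid)
    di <- which.max(fx$colony_dist_km[i])      # first max: stated tie-break
    distal_idx[tid] <- di
    leg <- rep("outbound", length(i))
    leg[seq_along(i) > di] <- "inbound"
    dd <- haversine_km(c(fx$lon[i][di], fx$lat[i][di]),
                       cbind(fx$lon[i], fx$lat[i]))
    fx$leg[i] <- leg
    fx$distal_signed_km[i] <- ifelse(leg == "outbound", -dd, dd)
  }
  if (!is_obj) return(fx)
  trips$fixes <- fx
  trips$trips$distal_index <- distal_idx[trips$trips$trip_id]
  trips
}

#' Interpolate a trip's positions to a 1-second grid
#'
#' Fits a natural cubic spline independently to `lon(t)` and `lat(t)` and
#' evaluates it on the 1-s grid spanning the trip, reproducing the original
#' fixes exactly at their own timestamps. Trips with fewer than four fixes
#' (insufficient support for a cubic spline) fall back to linear
#' interpolation with a message.
#'
#' @param trip Data frame for a single trip: `timestamp` (`POSIXct`, strictly
#'   increasing), `lon`, `lat`.
#' @param step_s Grid step in seconds (default 1).
#' @return Data frame `timestamp`, `lon`, `lat` on the dense grid.
#' @export
interpolate_1s <- function(trip, step_s = 1) {
  stopifnot(is.data.frame(trip),
            all(c("timestamp", "lon", "lat") %in% names(trip)))
  tt <- as.numeric(trip$timestamp)
  if (length(tt) < 2L) stop("need at least two fixes to interpolate")
  if (is.unsorted(tt, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  grid <- seq(tt[1], tt[length(tt)], by = step_s)
  if (length(tt) >= 4L) {
    fl <- stats::splinefun(tt, trip$lon, method = "natural")
    fa <- stats::splinefun(tt, trip$lat, method = "natural")
    lon <- fl(grid); lat <- fa(grid)
  } else {
    message("fewer than 4 fixes: falling back to linear interpolation")
    lon <- stats::approx(tt, trip$lon, xout = grid)$y
    lat <- stats::approx(tt, trip$lat, xout = grid)$y
  }
  data.frame(timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
             lon = lon, lat = lat)
}

#' Densify an annotated trip for dive georeferencing
#'
#' Runs [interpolate_1s()] on one trip and carries colony distance and leg
#' onto the dense grid: colony distance is recomputed from the interpolated
#' positions, and points up to the distal fix's timestamp inherit the
#' outbound leg, later points the inbound leg.
#'
#' @param trip A single trip's fixes with `timestamp`, `lon`, `lat`,
#'   `colony_dist_km`, `leg` (from [annotate_legs()]).
#' @param colony Colony `c(lon, lat)`.
#' @inheritParams interpolate_1s
#' @return Dense data frame `timestamp`, `lon`, `lat`, `colony_dist_km`,
#'   `leg` (and `bird_id`/`trip_id` if present on the input).
#' @export
densify_trip <- function(trip, colony, step_s = 1) {
  stopifnot("leg" %in% names(trip))
  dense <- interpolate_1s(trip[, c("timestamp", "lon", "lat")], step_s)
  dense$colony_dist_km <- haversine_km(as_lonlat(colony),
                                       cbind(dense$lon, dense$lat))
  t_distal <- trip$timestamp[which.max(trip$colony_dist_km)]
  dense$leg <- factor(
    ifelse(as.numeric(dense$timestamp) <= as.numeric(t_distal),
           "outbound", "inbound"),
    levels = c("outbound", "inbound"))
  for (cl in c("bird_id", "trip_id"))
    if (cl %in% names(trip)) dense[[cl]] <- trip[[cl]][1]
  dense
}
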