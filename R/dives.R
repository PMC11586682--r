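#' Detect dive events from a pressure series
#'
#' A dive is a submergence deeper than `threshold_m` (strictly: a sample at
#' exactly the threshold is surface behaviour). Two logger dialects are
#' supported:
#' \describe{
#'   \item{continuous_1hz}{regular sampling over the whole deployment; a
#'     dive is a maximal run of consecutive samples with depth >
#'     `threshold_m`. Duration is the run's time span plus one sampling
#'     interval, so a single-sample dive lasts one interval rather than 0 s
#'     (depth exceeded the threshold throughout that interval).}
#'   \item{event_10hz}{the logger only records bursts around submergence;
#'     each burst (separated from the next by a gap > 1 s) is one candidate
#'     event, retained when its maximum depth exceeds `threshold_m`.}
#' }
#'
#' @param samples Data frame with `timestamp` (`POSIXct`, non-decreasing
#'   within bird) and `depth_m`; an optional `bird_id` column is processed
#'   per bird.
#' @param threshold_m Dive threshold in metres (default 1.5).
#' @param dialect Sampling dialect, see Details.
#' @return Data frame of dive events: `bird_id` (if present), `start`,
#'   `end` (first/last sample time of the event), `duration_s`,
#'   `max_depth_m`, `n_samples`.
#' @export
detect_dives <- function(samples, threshold_m = 1.5,
                         dialect = c("continuous_1hz", "event_10hz")) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(samples),
            all(c("timestamp", "depth_m") %in% names(samples)))
  empty <- data.frame(bird_id = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      duration_s = numeric(0), max_depth_m = numeric(0),
                      n_samples = integer(0))
  if (nrow(samples) == 0L) return(empty)
  has_bird <- "bird_id" %in% names(samples)
  groups <- if (has_bird) split(samples, samples$bird_id) else list(all = samples)
  out <- lapply(names(groups), function(g) {
    s <- groups[[g]]
    tt <- as.numeric(s$timestamp)
    if (is.unsorted(tt)) stop("pressure samples must be sorted in time")
    ev <- if (dialect == "continuous_1hz") {
      scan_runs(tt, s$depth_m, threshold_m)
    } else {
      scan_bursts(tt, s$depth_m, threshold_m)
    }
    if (nrow(ev) && has_bird) ev$bird_id <- g
    ev
  })
  out <- out[vapply(out, nrow, 0L) > 0]
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res$start <- as.POSIXct(res$start, origin = "1970-01-01", tz = "UTC")
  res$end <- as.POSIXct(res$end, origin = "1970-01-01", tz = "UTC")
  cols <- c(if (has_bird) "bird_id", "start", "end", "duration_s",
            "max_depth_m", "n_samples")
  res[, cols, drop = FALSE]
}

# maximal runs of depth strictly above threshold (continuous dialect)
scan_runs <- function(tt, depth, thr) {
  wet <- depth > thr
  if (!any(wet)) return(data.frame())
  r <- rle(wet)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- if (length(tt) > 1L) stats::median(diff(tt)) else 1
  idx <- which(r$values)
  data.frame(
    start = tt[starts[idx]],
    end = tt[ends[idx]],
    duration_s = tt[ends[idx]] - tt[starts[idx]] + iv,
    max_depth_m = vapply(idx, function(j) max(depth[starts[j]:ends[j]]), 0),
    n_samples = r$lengths[idx])
}

# bursts separated by > 1 s gaps, filtered by max depth (event dialect)
scan_bursts <- function(tt, depth, thr) {
  burst <- cumsum(c(0, diff(tt) > 1))
  res <- do.call(rbind, lapply(split(seq_along(tt), burst), function(i) {
    data.frame(start = tt[i[1]], end = tt[i[length(i)]],
               duration_s = tt[i[length(i)]] - tt[i[1]] +
                 if (length(i) > 1L) stats::median(diff(tt[i])) else 0.1,
               max_depth_m = max(depth[i]), n_samples = length(i))
  }))
  res[res$max_depth_m > thr, , drop = FALSE]
}

#' Georeference dives to a densified track
#'
#' Matches each dive to the dense (1-s) track point with the smallest
#' absolute time difference to the dive start. Dives whose best match is
#' more than `tolerance_s` away (for example because the GPS battery died
#' before the TDR) are retained with `matched = FALSE` and should be
#' excluded from analysis. Matched dives inherit the track point's position,
#' colony distance and leg. When both inputs carry `bird_id`, matching is
#' done within bird.
#'
#' @param dives Dive events from [detect_dives()].
#' @param dense_track Densified track from [densify_trip()] (columns
#'   `timestamp`, `lon`, `lat`, `colony_dist_km`, `leg`, optionally
#'   `bird_id`, `trip_id`); several trips may be row-bound.
#' @param tolerance_s Maximum accepted |time difference| in seconds
#'   (default 1; a mismatch of exactly 1 s is accepted).
#' @return `dives` with added columns `matched`, `dt_s`, `lon`, `lat`,
#'   `colony_dist_km`, `leg` and (when available) `trip_id`.
#' @export
georeference_dives <- function(dives, dense_track, tolerance_s = 1) {
  stopifnot(is.data.frame(dives))
  dives$matched <- FALSE
  dives$dt_s <- NA_real_
  dives$lon <- dives$lat <- dives$colony_dist_km <- NA_real_
  dives$leg <- factor(NA_character_, levels = c("outbound", "inbound"))
  if ("trip_id" %in% names(dense_track)) dives$trip_id <- NA_character_
  if (nrow(dives) == 0L || is.null(dense_track) || nrow(dense_track) == 0L)
    return(dives)
  by_bird <- "bird_id" %in% names(dives) && "bird_id" %in% names(dense_track)
  for (b in if (by_bird) unique(dives$bird_id) else "all") {
    di <- if (by_bird) which(dives$bird_id == b) else seq_len(nrow(dives))
    tr <- if (by_bird) dense_track[dense_track$bird_id == b, , drop = FALSE]
          else dense_track
    if (nrow(tr) == 0L || length(di) == 0L) next
    tt <- as.numeric(tr$timestamp)
    o <- order(tt); tt <- tt[o]; tr <- tr[o, , drop = FALSE]
    ts <- as.numeric(dives$start[di])
    lo <- pmin(pmax(findInterval(ts, tt), 1L), length(tt))
    hi <- pmin(lo + 1L, length(tt))
    j <- ifelse(abs(tt[lo] - ts) <= abs(tt[hi] - ts), lo, hi)
    dt <- tt[j] - ts
    ok <- abs(dt) <= tolerance_s
    dives$dt_s[di] <- dt
    dives$matched[di] <- ok
    dives$lon[di[ok]] <- tr$lon[j[ok]]
    dives$lat[di[ok]] <- tr$lat[j[ok]]
    dives$colony_dist_km[di[ok]] <- tr$colony_dist_km[j[ok]]
    dives$leg[di[ok]] <- tr$leg[j[ok]]
    if ("trip_id" %in% names(tr)) dives$trip_id[di[ok]] <- tr$trip_id[j[ok]]
  }
  dives
}
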