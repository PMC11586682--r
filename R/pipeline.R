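#' Clean raw GPS fixes into leg-annotated complete trips
#'
#' Convenience wrapper chaining the track-processing steps: optional
#' civil-twilight night filtering, trip splitting around the colony buffer
#' and distal-point leg assignment. Only complete trips (colony contact on
#' both ends) are kept in the returned fixes.
#'
#' @param gps Data frame `bird_id`, `timestamp`, `lon`, `lat`.
#' @param colony Colony `c(lon, lat)`.
#' @param buffer_km Colony buffer radius (default 2 km).
#' @param night_filter Apply [filter_daylight()] first?
#' @return A `cpf_trips` object (see [split_trips()]) restricted to
#'   complete trips, with legs annotated.
#' @export
process_tracks <- function(gps, colony, buffer_km = 2, night_filter = TRUE) {
  if (night_filter) gps <- filter_daylight(gps)
  tr <- split_trips(gps, colony, buffer_km)
  keep <- tr$trips$trip_id[tr$trips$complete]
  tr$fixes <- tr$fixes[tr$fixes$trip_id %in% keep, , drop = FALSE]
  tr$trips <- tr$trips[tr$trips$complete, , drop = FALSE]
  rownames(tr$fixes) <- rownames(tr$trips) <- NULL
  annotate_legs(tr)
}

#' Per-fix model table with a dive indicator
#'
#' Builds the input of [fit_dive_probability()]: one row per analysed fix
#' with `dive = 1` when at least one matched dive starts within half a fix
#' interval of the fix's timestamp (same bird), plus colony distance, leg,
#' time of day and any metadata columns present (`sex`, `year`).
#'
#' @param trips An annotated `cpf_trips` object from [process_tracks()].
#' @param dives Matched dives from [georeference_dives()] (rows with
#'   `matched = FALSE` are ignored).
#' @param meta Optional per-bird metadata data frame (`bird_id`, `sex`,
#'   `year`).
#' @param window_s Half-window for fix-dive association (default 30 s).
#' @return Data frame `bird_id`, `trip_id`, `timestamp`, `colony_dist_km`,
#'   `leg`, `tod_h`, `dive` (+ metadata columns).
#' @export
build_fix_table <- function(trips, dives, meta = NULL, window_s = 30) {
  fx <- trips$fixes
  fx$dive <- 0L
  dv <- dives[dives$matched, , drop = FALSE]
  for (b in unique(dv$bird_id)) {
    fi <- which(fx$bird_id == b)
    if (length(fi) == 0L) next
    ts <- as.numeric(fx$timestamp[fi])
    for (t0 in as.numeric(dv$start[dv$bird_id == b])) {
      j <- which.min(abs(ts - t0))
      if (abs(ts[j] - t0) <= window_s) fx$dive[fi[j]] <- 1L
    }
  }
  fx$tod_h <- tod_hours(fx$timestamp)
  out <- fx[, c("bird_id", "trip_id", "timestamp", "colony_dist_km",
                "leg", "tod_h", "dive")]
  if (!is.null(meta)) out <- merge(out, meta, by = "bird_id", sort = FALSE)
  out
}

#' Per-dive model table
#'
#' Builds the input of [fit_depth_model()] / [fit_duration_model()] from
#' matched, georeferenced dives: depth, duration, colony distance, leg,
#' time of day and per-bird metadata.
#'
#' @inheritParams build_fix_table
#' @return Data frame `bird_id`, `depth_m`, `duration_s`,
#'   `colony_dist_km`, `leg`, `tod_h` (+ metadata columns).
#' @export
build_dive_table <- function(dives, meta = NULL) {
  dv <- dives[dives$matched, , drop = FALSE]
  out <- data.frame(bird_id = dv$bird_id,
                    depth_m = dv$max_depth_m,
                    duration_s = dv$duration_s,
                    colony_dist_km = dv$colony_dist_km,
                    leg = dv$leg,
                    tod_h = tod_hours(dv$start))
  if (!is.null(meta)) out <- merge(out, meta, by = "bird_id", sort = FALSE)
  out
}

tod_hours <- function(t) {
  (as.numeric(t) %% 86400) / 3600
}

#' Run the full synthetic pipeline
#'
#' Simulates every data stream from one configuration and pushes it through
#' the whole analysis chain: track cleaning and trip splitting, 1-s track
#' densification, dive detection and georeferencing, and assembly of the
#' per-fix and per-dive model tables. Used for end-to-end testing and for
#' reproducing the halo-shaped dive distribution on synthetic data.
#'
#' @param config A [sim_config()].
#' @param dialect TDR dialect passed to [simulate_tdr()].
#' @param night_filter Apply the civil-twilight filter (default TRUE).
#' @return List: `tracks` (raw simulated fixes), `trips` (processed
#'   `cpf_trips`), `tdr` (simulated TDR with ground truth), `dives`
#'   (detected, georeferenced dives), `fix_table`, `dive_table`, `meta`.
#' @export
sim_pipeline <- function(config, dialect = "continuous_1hz",
                         night_filter = TRUE) {
  tracks <- simulate_tracks(config)
  meta <- unique(tracks[, c("bird_id", "sex", "year")])
  trips <- process_tracks(tracks[, c("bird_id", "timestamp", "lon", "lat")],
                          config$colony, night_filter = night_filter)
  tdr <- simulate_tdr(tracks, config, dialect = dialect)
  dives <- detect_dives(tdr$samples, dialect = dialect)
  dense <- do.call(rbind, lapply(split(trips$fixes, trips$fixes$trip_id),
                                 densify_trip, colony = config$colony))
  rownames(dense) <- NULL
  dives <- georeference_dives(dives, dense)
  list(tracks = tracks, trips = trips, tdr = tdr, dives = dives,
       fix_table = build_fix_table(trips, dives, meta),
       dive_table = build_dive_table(dives, meta),
       meta = meta)
}
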