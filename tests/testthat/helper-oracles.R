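# Independent brute-force oracles used to cross-check the implementation.

# explicit linear scan for maximal above-threshold runs, written
# independently of the rle-based detector
brute_force_dives <- function(tt, depth, thr = 1.5) {
  n <- length(depth)
  iv <- if (n > 1) stats::median(diff(tt)) else 1
  ev <- list()
  for (i in seq_len(n)) {
    if (depth[i] > thr && (i == 1L || depth[i - 1] <= thr)) {
      j <- i
      while (j < n && depth[j + 1] > thr) j <- j + 1L
      ev[[length(ev) + 1L]] <- data.frame(
        start = tt[i], end = tt[j], duration_s = tt[j] - tt[i] + iv,
        max_depth_m = max(depth[i:j]), n_samples = j - i + 1L)
    }
  }
  if (!length(ev)) return(data.frame())
  do.call(rbind, ev)
}

# linear scan over a distance series: runs above the buffer and whether each
# is bracketed by in-buffer fixes
trip_runs_oracle <- function(dist, buffer) {
  away <- dist > buffer
  n <- length(away)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (away[i]) {
      j <- i
      while (j < n && away[j + 1]) j <- j + 1L
      runs[[length(runs) + 1L]] <-
        list(start = i, end = j, complete = i > 1L && j < n)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# stationary distribution of a row-stochastic matrix by eigen-decomposition
stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# place points due east of a colony at the equator so that colony distance
# equals the requested km values (1 deg of longitude = 111.19493 km)
equator_track <- function(dist_km, t0 = as.POSIXct("2012-07-01 10:00:00",
                                                   tz = "UTC"),
                          bird = "B1", step_s = 60) {
  data.frame(bird_id = bird,
             timestamp = t0 + seq_along(dist_km) * step_s,
             lon = dist_km / 111.19493, lat = 0)
}

equator_colony <- c(0, 0)
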