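#' Simulate GPS tracks of central-place foraging trips
#'
#' Generates per-bird foraging trips as a three-state (travel/forage/rest)
#' first-order correlated random walk from the colony: state-dependent
#' Gaussian ground speed (truncated at 0) and wrapped-Cauchy turning angles,
#' with a weak outward heading bias on the travel state during the outbound
#' phase (directed commuting) and a homing bias that activates once the
#' outbound step budget is spent, so the distal point is induced by the
#' trip-duration budget rather than imposed. Each trip starts and ends with
#' in-buffer fixes near the colony so that downstream trip splitting sees a
#' complete colony-to-colony trip.
#'
#' The per-fix latent state, phase-based leg and true colony distance are
#' returned as ground truth for recovery testing; they are not used by the
#' processing pipeline, which re-derives everything from timestamps and
#' positions.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with one row per fix: `bird_id`, `trip`, `timestamp`
#'   (UTC `POSIXct`), `lon`, `lat`, `sex`, `year`, and ground-truth columns
#'   `state_true`, `leg_true` (`NA` for in-buffer fixes) and `dist_true_km`.
#'   Identical for identical configs (seed included).
#' @export
simulate_tracks <- function(config) {
  validate_config(config)
  set.seed(child_seed(config$rng_seed, "tracks"))
  st <- states()
  sexes <- rep_len(c("female", "male"), config$n_birds)
  # years in blocks so sex and year are not confounded across birds
  years <- rep(c(2012L, 2013L), length.out = config$n_birds,
               each = max(1L, ceiling(config$n_birds / 2)))
  out <- list()
  for (b in seq_len(config$n_birds)) {
    bird <- sprintf("B%02d", b)
    for (k in seq_len(config$trips_per_bird)) {
      day <- 1L + ((b * 3L + k * 5L) %% 25L)
      t0 <- as.POSIXct(sprintf("%d-07-%02d 00:00:00", years[b], day),
                       tz = "UTC") + config$start_hour * 3600
      tr <- sim_one_trip(config, t0)
      tr$bird_id <- bird; tr$trip <- k
      tr$sex <- sexes[b]; tr$year <- years[b]
      out[[paste(bird, k)]] <- tr
    }
  }
  fixes <- do.call(rbind, c(out, make.row.names = FALSE))
  fixes[, c("bird_id", "trip", "timestamp", "lon", "lat", "sex", "year",
            "state_true", "leg_true", "dist_true_km")]
}

# one trip as a correlated random walk in local (km) coordinates
sim_one_trip <- function(cfg, t0) {
  dt <- cfg$fix_interval
  max_steps <- 8L * cfg$trip_fixes
  n_cap <- max_steps + 8L
  x <- y <- numeric(n_cap)
  state <- character(n_cap)
  phase <- character(n_cap)

  # two pre-departure fixes rafting inside the buffer
  r0 <- stats::runif(1, 0.2, 0.8); a0 <- stats::runif(1, 0, 2 * pi)
  x[1] <- r0 * sin(a0); y[1] <- r0 * cos(a0)
  x[2] <- x[1] + stats::rnorm(1, 0, 0.02)
  y[2] <- y[1] + stats::rnorm(1, 0, 0.02)
  state[1:2] <- "rest"; phase[1:2] <- "colony"

  heading <- stats::runif(1, 0, 2 * pi)
  s <- "travel"
  i <- 2L
  homing <- FALSE
  arrived <- FALSE
  nstep <- 0L
  while (nstep < max_steps) {
    nstep <- nstep + 1L
    i <- i + 1L
    s <- sample(states(), 1L, prob = cfg$state_transition[s, ])
    spd <- max(0, stats::rnorm(1, cfg$speed_mean[s], cfg$speed_sd[s]))
    heading <- heading + rwrapcauchy(1, cfg$turn_rho[s])
    if (nstep > cfg$trip_fixes) homing <- TRUE
    if (homing) {
      heading <- blend_heading(heading, atan2(-x[i - 1], -y[i - 1]),
                               cfg$homing_bias)
    } else if (s == "travel") {
      heading <- blend_heading(heading, atan2(x[i - 1], y[i - 1]),
                               cfg$outward_bias)
    }
    step <- spd * dt / 1000
    x[i] <- x[i - 1] + step * sin(heading)
    y[i] <- y[i - 1] + step * cos(heading)
    state[i] <- s
    phase[i] <- if (homing) "inbound" else "outbound"
    if (homing && sqrt(x[i]^2 + y[i]^2) <= 1.0) { arrived <- TRUE; break }
  }
  if (arrived) {  # two post-arrival fixes rafting inside the buffer
    for (j in 1:2) {
      i <- i + 1L
      x[i] <- x[i - 1] * 0.5 + stats::rnorm(1, 0, 0.02)
      y[i] <- y[i - 1] * 0.5 + stats::rnorm(1, 0, 0.02)
      state[i] <- "rest"; phase[i] <- "colony"
    }
  }
  n <- i
  ll <- unproject_aeq(cbind(x[1:n], y[1:n]), cfg$colony)
  data.frame(
    timestamp = t0 + (seq_len(n) - 1L) * dt,
    lon = ll[, "lon"], lat = ll[, "lat"],
    state_true = state[1:n],
    leg_true = ifelse(phase[1:n] == "colony", NA_character_, phase[1:n]),
    dist_true_km = haversine_km(cfg$colony, ll))
}

# wrapped Cauchy deviates centred on 0 with mean resultant length rho
rwrapcauchy <- function(n, rho) {
  if (rho <= 0) return(stats::runif(n, -pi, pi))
  if (rho >= 1) return(rep(0, n))
  u <- stats::runif(n, -0.5, 0.5)
  2 * atan((1 - rho) / (1 + rho) * tan(pi * u))
}

# circular convex combination of two headings (radians)
blend_heading <- function(h, target, w) {
  atan2((1 - w) * sin(h) + w * sin(target),
        (1 - w) * cos(h) + w * cos(target))
}

#' Simulate a time-depth recorder stream with ground-truth dives
#'
#' Dives occur only at forage-state fixes, with per-fix probability
#' `plogis(halo_beta0 + halo_beta1 * distance_km)`. Each dive's maximum
#' depth is `depth_alpha + depth_slope * distance_km + depth_sex_effect *
#' male + N(0, depth_noise_sd)`, truncated above 1.51 m so every dive
#' exceeds the 1.5-m detection threshold; durations are log-normal and
#' independent of all covariates. The dive's depth profile is a scaled
#' half-sine whose maximum equals the ground-truth maximum depth.
#'
#' @param tracks Output of [simulate_tracks()].
#' @param config The same [sim_config()].
#' @param dialect `"continuous_1hz"` (1-s samples over the whole trip,
#'   surface depth 0) or `"event_10hz"` (0.1-s samples only during dives).
#' @param noise_sd Gaussian measurement noise (m) added to every pressure
#'   sample (default 0).
#' @return List with `samples` (data frame `bird_id`, `trip`, `timestamp`,
#'   `depth_m`), `truth` (one row per dive: `bird_id`, `trip`, `fix_time`,
#'   `start`, `end`, `duration_s`, `max_depth_m`, `dist_true_km`,
#'   `leg_true`) and `dialect`.
#' @export
simulate_tdr <- function(tracks, config,
                         dialect = c("continuous_1hz", "event_10hz"),
                         noise_sd = 0) {
  dialect <- match.arg(dialect)
  validate_config(config)
  set.seed(child_seed(config$rng_seed, "tdr"))
  dt <- config$fix_interval
  cand <- which(tracks$state_true == "forage" & !is.na(tracks$leg_true))
  p <- stats::plogis(config$halo_beta0 +
                     config$halo_beta1 * tracks$dist_true_km[cand])
  divers <- cand[stats::rbinom(length(cand), 1L, p) == 1L]

  dmax <- max(2, min(58, floor(dt) - 2))
  dur <- pmin(dmax, pmax(2, round(stats::rlnorm(
    length(divers), config$dive_duration_meanlog, config$dive_duration_sdlog))))
  off <- vapply(dur, function(d) sample.int(max(1L, floor(dt) - d - 1L), 1L),
                integer(1))
  mu <- config$depth_alpha +
    config$depth_slope * tracks$dist_true_km[divers] +
    config$depth_sex_effect * (tracks$sex[divers] == "male")
  md <- rtnorm_above(length(divers), mu, config$depth_noise_sd, 1.51)

  truth <- data.frame(
    bird_id = tracks$bird_id[divers],
    trip = tracks$trip[divers],
    fix_time = tracks$timestamp[divers],
    start = tracks$timestamp[divers] + off,
    duration_s = dur,
    max_depth_m = md,
    dist_true_km = tracks$dist_true_km[divers],
    leg_true = tracks$leg_true[divers])
  truth$end <- truth$start + truth$duration_s - 1
  truth <- truth[order(truth$bird_id, truth$start), ]
  rownames(truth) <- NULL

  samples <- if (dialect == "continuous_1hz") {
    tdr_continuous(tracks, truth, noise_sd)
  } else {
    tdr_event(truth, noise_sd)
  }
  list(samples = samples, truth = truth, dialect = dialect)
}

# half-sine dive profile at m points, peaking exactly at max_depth
dive_profile <- function(max_depth, m, shift = 0) {
  raw <- sin(pi * (seq_len(m) - shift) / (m + 1 - 2 * shift))
  1.6 + (max_depth - 1.6) * raw / max(raw)
}

tdr_continuous <- function(tracks, truth, noise_sd) {
  out <- list()
  key <- interaction(tracks$bird_id, tracks$trip, drop = TRUE)
  for (g in levels(key)) {
    tf <- tracks[key == g, ]
    t0 <- as.numeric(tf$timestamp[1])
    t1 <- as.numeric(tf$timestamp[nrow(tf)])
    tt <- seq(t0, t1, by = 1)
    depth <- numeric(length(tt))
    tg <- truth[truth$bird_id == tf$bird_id[1] & truth$trip == tf$trip[1], ]
    for (j in seq_len(nrow(tg))) {
      i0 <- as.numeric(tg$start[j]) - t0 + 1
      d <- tg$duration_s[j]
      depth[i0:(i0 + d - 1)] <- dive_profile(tg$max_depth_m[j], d)
    }
    if (noise_sd > 0) depth <- depth + stats::rnorm(length(tt), 0, noise_sd)
    out[[g]] <- data.frame(
      bird_id = tf$bird_id[1], trip = tf$trip[1],
      timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
      depth_m = depth)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

tdr_event <- function(truth, noise_sd) {
  out <- vector("list", nrow(truth))
  for (j in seq_len(nrow(truth))) {
    d <- truth$duration_s[j]
    tt <- as.numeric(truth$start[j]) + seq(0, d - 0.1, by = 0.1)
    depth <- dive_profile(truth$max_depth_m[j], length(tt), shift = 0.5)
    if (noise_sd > 0) depth <- depth + stats::rnorm(length(tt), 0, noise_sd)
    out[[j]] <- data.frame(
      bird_id = truth$bird_id[j], trip = truth$trip[j],
      timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
      depth_m = depth)
  }
  if (length(out) == 0L)
    return(data.frame(bird_id = character(0), trip = integer(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      depth_m = numeric(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Gaussian truncated below at `lo` (rejection with a safe fallback)
rtnorm_above <- function(n, mu, sd, lo) {
  x <- stats::rnorm(n, mu, sd)
  for (it in 1:50) {
    bad <- x <= lo
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mu[bad], sd)
  }
  x[x <= lo] <- lo + stats::rexp(sum(x <= lo), 10)
  x
}

#' Simulate bird-borne camera frames
#'
#' One still frame per GPS fix; the conspecific-present flag is Bernoulli
#' with probability `social_p[state, leg]` from the configuration, so
#' sociality can differ between behaviours and between the outbound and
#' inbound legs. An optional dropout removes the trailing fraction of each
#' bird's frames, emulating camera battery death.
#'
#' @inheritParams simulate_tdr
#' @param dropout Fraction (0-1) of trailing frames removed per bird.
#' @return Data frame `bird_id`, `timestamp`, `social` (logical),
#'   `n_conspecifics` (`NA` when not social).
#' @export
simulate_camera <- function(tracks, config, dropout = 0) {
  validate_config(config)
  stopifnot(dropout >= 0, dropout < 1)
  set.seed(child_seed(config$rng_seed, "camera"))
  leg <- ifelse(is.na(tracks$leg_true), "outbound", tracks$leg_true)
  p <- config$social_p[cbind(tracks$state_true, leg)]
  social <- stats::rbinom(nrow(tracks), 1L, p) == 1L
  frames <- data.frame(
    bird_id = tracks$bird_id,
    timestamp = tracks$timestamp,
    social = social,
    n_conspecifics = ifelse(social, 1L + stats::rpois(nrow(tracks), 1), NA_integer_))
  if (dropout > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(frames)), frames$bird_id),
                          function(i) i[seq_len(ceiling(length(i) * (1 - dropout)))]))
    frames <- frames[sort(keep), , drop = FALSE]
    rownames(frames) <- NULL
  }
  frames
}

#' Simulate colony departure/arrival flock observations
#'
#' Each observed movement unit is a singleton with the configured
#' per-direction probability, otherwise a flock of size `2 + NB(mu, size)`,
#' giving right-skewed flock sizes whose mean and spread can differ between
#' departures and arrivals.
#'
#' @param config A [sim_config()].
#' @return Data frame `direction` (factor outbound/inbound) and `size`
#'   (integer >= 1).
#' @export
simulate_flocks <- function(config) {
  validate_config(config)
  set.seed(child_seed(config$rng_seed, "flocks"))
  out <- lapply(c("outbound", "inbound"), function(dir) {
    n <- config$n_flock_obs[[dir]]
    single <- stats::rbinom(n, 1L, config$flock_singleton_p[[dir]]) == 1L
    size <- ifelse(single, 1L,
                   2L + stats::rnbinom(n, size = config$flock_size[[dir]],
                                       mu = config$flock_mu[[dir]]))
    data.frame(direction = factor(dir, levels = c("outbound", "inbound")),
               size = as.integer(size))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
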