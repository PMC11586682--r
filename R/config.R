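#' Configuration for the central-place foraging simulator
#'
#' Bundles and validates every parameter of the synthetic data generators:
#' a three-state (travel/forage/rest) correlated random walk from a colony,
#' a distance-dependent "halo" of dive probability and depth, leg- and
#' behaviour-dependent conspecific detections on bird-borne cameras, and
#' flock-size mixtures for colony departures and arrivals.
#'
#' The dive-intensity halo is logistic on the per-fix scale:
#' `P(dive | forage fix) = plogis(halo_beta0 + halo_beta1 * distance_km)`,
#' so a positive `halo_beta1` concentrates diving away from the colony, the
#' pattern expected when conspecifics deplete prey near a large breeding
#' colony (Ashmole's halo). Maximum dive depth is linear in colony distance
#' with an additive sex offset and Gaussian noise.
#'
#' @param colony Colony position `c(lon, lat)` in decimal degrees; the
#'   default is a large northern-gannet colony in the Celtic Sea
#'   (51.7167 N, 5.4667 W).
#' @param n_birds,trips_per_bird Number of simulated birds and complete
#'   foraging trips per bird.
#' @param fix_interval GPS fix interval in seconds (default 60).
#' @param state_transition 3x3 row-stochastic matrix over
#'   (travel, forage, rest), one row per current state.
#' @param speed_mean,speed_sd Per-state ground-speed mean and sd (m/s);
#'   speeds are Gaussian truncated at 0.
#' @param turn_rho Per-state mean resultant length (0-1) of the wrapped
#'   Cauchy turning-angle distribution; 1 = straight-line persistence.
#' @param halo_beta0,halo_beta1 Intercept and slope (per km) of the logistic
#'   dive-intensity function of colony distance.
#' @param depth_alpha Baseline maximum dive depth (m); must exceed the 1.5-m
#'   dive-detection threshold.
#' @param depth_slope Depth increase per km of colony distance (m/km).
#' @param depth_sex_effect Additive depth offset (m) for males (negative =
#'   males shallower).
#' @param depth_noise_sd Gaussian sd of depth noise (m); depths are truncated
#'   above 1.51 m so every simulated dive is detectable.
#' @param dive_duration_meanlog,dive_duration_sdlog Log-normal parameters of
#'   dive duration (s); duration is independent of all covariates.
#' @param social_p 3x2 matrix of per-frame conspecific detection
#'   probabilities, rows = states (travel, forage, rest), columns = legs
#'   (outbound, inbound).
#' @param flock_singleton_p Named probabilities (outbound, inbound) that a
#'   departing/arriving movement unit is a single bird.
#' @param flock_mu,flock_size Negative-binomial mean and dispersion of the
#'   flock-size excess over 2 for non-singleton units, per direction.
#' @param n_flock_obs Number of observed movement units per direction.
#' @param trip_fixes Outbound step budget (fixes) before the homing bias
#'   activates, inducing the distal point.
#' @param outward_bias,homing_bias Weight (0-1) pulling the travel-state
#'   heading radially away from (outbound phase) or back towards (homing
#'   phase) the colony.
#' @param start_hour UTC hour at which trips depart.
#' @param rng_seed Master seed; per-stream child seeds are derived from it
#'   deterministically.
#' @return A validated list of class `cpf_config`.
#' @export
sim_config <- function(
  colony = c(lon = -5.4667, lat = 51.7167),
  n_birds = 8L,
  trips_per_bird = 1L,
  fix_interval = 60,
  state_transition = matrix(c(0.90, 0.07, 0.03,
                              0.15, 0.75, 0.10,
                              0.10, 0.10, 0.80),
                            nrow = 3, byrow = TRUE,
                            dimnames = list(c("travel", "forage", "rest"),
                                            c("travel", "forage", "rest"))),
  speed_mean = c(travel = 14, forage = 4, rest = 0.3),
  speed_sd = c(travel = 2, forage = 1.5, rest = 0.2),
  turn_rho = c(travel = 0.95, forage = 0.3, rest = 0),
  halo_beta0 = -4,
  halo_beta1 = 0.02,
  depth_alpha = 6,
  depth_slope = 0.008,
  depth_sex_effect = -1.272,
  depth_noise_sd = 2,
  dive_duration_meanlog = log(12),
  dive_duration_sdlog = 0.4,
  social_p = matrix(c(0.072, 0.253,
                      0.138, 0.201,
                      0.064, 0.029),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(c("travel", "forage", "rest"),
                                    c("outbound", "inbound"))),
  flock_singleton_p = c(outbound = 0.49, inbound = 0.316),
  flock_mu = c(outbound = 1.16, inbound = 6.85),
  flock_size = c(outbound = 5, inbound = 1.2),
  n_flock_obs = c(outbound = 295L, inbound = 209L),
  trip_fixes = 480L,
  outward_bias = 0.3,
  homing_bias = 0.5,
  start_hour = 6,
  rng_seed = 1L) {

  if (is.matrix(state_transition) && is.null(dimnames(state_transition)))
    dimnames(state_transition) <- list(states(), states())
  cfg <- structure(as.list(environment()), class = "cpf_config")
  validate_config(cfg)
  cfg
}

states <- function() c("travel", "forage", "rest")

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cpf_config"))
  as_lonlat(cfg$colony)
  tm <- cfg$state_transition
  if (!is.matrix(tm) || !all(dim(tm) == c(3L, 3L)))
    stop("state_transition must be a 3x3 matrix")
  if (any(tm < 0) || any(tm > 1))
    stop("state_transition entries must be probabilities in [0, 1]")
  if (any(abs(rowSums(tm) - 1) > 1e-12))
    stop("state_transition rows must each sum to 1 (tolerance 1e-12)")
  if (!all(states() %in% names(cfg$speed_mean)) ||
      !all(states() %in% names(cfg$speed_sd)) ||
      !all(states() %in% names(cfg$turn_rho)))
    stop("speed_mean, speed_sd and turn_rho must be named by state")
  if (cfg$fix_interval <= 0) stop("fix_interval must be positive")
  if (cfg$depth_alpha <= 1.5)
    stop("depth_alpha must exceed the 1.5-m detection threshold")
  probs <- c(cfg$social_p, cfg$flock_singleton_p,
             plogis(cfg$halo_beta0))
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(dim(cfg$social_p) == c(3L, 2L)))
    stop("social_p must be 3 states x 2 legs")
  invisible(cfg)
}

#' @export
print.cpf_config <- function(x, ...) {
  cat("cpf_config:", x$n_birds, "birds x", x$trips_per_bird,
      "trips; fix interval", x$fix_interval, "s\n")
  cat("  halo: logit p(dive) =", x$halo_beta0, "+", x$halo_beta1,
      "* dist_km; depth =", x$depth_alpha, "+", x$depth_slope,
      "* dist_km (male", x$depth_sex_effect, "m)\n")
  cat("  seed:", x$rng_seed, "\n")
  invisible(x)
}

# deterministic child seed per named stream, kept below 2^31
child_seed <- function(seed, stream) {
  k <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) %% 65011 * 31013 + k * 7919 + 1) %% 2147483629)
}
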