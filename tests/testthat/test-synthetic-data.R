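test_that("generators are deterministic in the config seed", {
  cfg <- sim_config(n_birds = 2, trip_fixes = 60, rng_seed = 42)
  a <- simulate_tracks(cfg)
  b <- simulate_tracks(cfg)
  expect_identical(a, b)
  expect_identical(simulate_tdr(a, cfg)$samples, simulate_tdr(b, cfg)$samples)
  expect_identical(simulate_camera(a, cfg), simulate_camera(b, cfg))
  expect_identical(simulate_flocks(cfg), simulate_flocks(cfg))
})

test_that("a rest-only transition matrix never leaves the colony buffer", {
  P <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, byrow = TRUE)
  cfg <- sim_config(n_birds = 2, trip_fixes = 100, state_transition = P,
                    rng_seed = 5)
  tr <- simulate_tracks(cfg)
  expect_lt(max(tr$dist_true_km), 2)
  sp <- split_trips(tr[, c("bird_id", "timestamp", "lon", "lat")],
                    cfg$colony)
  expect_equal(sum(sp$trips$complete), 0)
})

test_that("config validation rejects a non-stochastic matrix and bad params", {
  P <- matrix(c(0.5, 0.5, 0.1, 0.2, 0.6, 0.2, 0.3, 0.3, 0.4), 3, byrow = TRUE)
  expect_error(sim_config(state_transition = P), "sum to 1")
  expect_error(sim_config(fix_interval = 0), "fix_interval")
  expect_error(sim_config(depth_alpha = 1.2), "depth_alpha")
  expect_error(simulate_tdr(data.frame(), sim_config(), dialect = "weird"))
})

test_that("latent state frequencies match the stationary distribution", {
  P <- matrix(c(0.5, 0.3, 0.2,
                0.2, 0.6, 0.2,
                0.3, 0.3, 0.4), 3, byrow = TRUE,
              dimnames = list(c("travel", "forage", "rest"),
                              c("travel", "forage", "rest")))
  cfg <- sim_config(n_birds = 1, trip_fixes = 10000, state_transition = P,
                    rng_seed = 9)
  tr <- simulate_tracks(cfg)
  st <- tr$state_true[!is.na(tr$leg_true) & tr$leg_true == "outbound"]
  n <- length(st)
  expect_gte(n, 9000)
  pi_hat <- table(factor(st, levels = c("travel", "forage", "rest"))) / n
  pi_true <- stationary_dist(P)
  for (k in 1:3) {
    se <- sqrt(pi_true[k] * (1 - pi_true[k]) / n)
    expect_lt(abs(pi_hat[k] - pi_true[k]), 3 * se)
  }
})

test_that("dive intensity follows the halo and depths exceed the threshold", {
  cfg0 <- sim_config(n_birds = 4, halo_beta1 = 0, halo_beta0 = -2,
                     rng_seed = 21)
  tr0 <- simulate_tracks(cfg0)
  td0 <- simulate_tdr(tr0, cfg0)
  forage <- tr0[tr0$state_true == "forage" & !is.na(tr0$leg_true), ]
  forage$dived <- as.integer(
    forage$timestamp %in% td0$truth$fix_time)
  sl <- summary(lm(dived ~ dist_true_km, data = forage))$coefficients
  expect_lt(abs(sl["dist_true_km", "Estimate"]),
            3 * sl["dist_true_km", "Std. Error"])

  cfg1 <- sim_config(n_birds = 4, rng_seed = 21)   # halo_beta1 = 0.02 > 0
  tr1 <- simulate_tracks(cfg1)
  td1 <- simulate_tdr(tr1, cfg1)
  expect_gt(mean(td1$truth$dist_true_km),
            mean(tr1$dist_true_km[!is.na(tr1$leg_true)]))
  expect_true(all(td1$truth$max_depth_m > 1.5))
  # halo property: dive distances stochastically greater than fix distances
  mw <- suppressWarnings(wilcox.test(
    td1$truth$dist_true_km, tr1$dist_true_km[!is.na(tr1$leg_true)],
    alternative = "greater"))
  expect_lt(mw$p.value, 0.01)
})

test_that("event-dialect pressure exists only inside ground-truth dives", {
  cfg <- sim_config(n_birds = 2, rng_seed = 13)
  tr <- simulate_tracks(cfg)
  td <- simulate_tdr(tr, cfg, dialect = "event_10hz")
  tt <- as.numeric(td$samples$timestamp)
  inside <- rep(FALSE, length(tt))
  for (j in seq_len(nrow(td$truth))) {
    s <- as.numeric(td$truth$start[j])
    inside <- inside |
      (td$samples$bird_id == td$truth$bird_id[j] &
         tt >= s - 1e-6 & tt <= s + td$truth$duration_s[j])
  }
  expect_true(all(inside))
})

test_that("camera social flags follow the configured (state, leg) rates", {
  cfg <- sim_config(n_birds = 2, rng_seed = 3,
                    social_p = matrix(0, 3, 2,
                                      dimnames = dimnames(sim_config()$social_p)))
  tr <- simulate_tracks(cfg)
  expect_equal(sum(simulate_camera(tr, cfg)$social), 0)
  cfg$social_p[] <- 1
  expect_true(all(simulate_camera(tr, cfg)$social))

  cfg2 <- sim_config(n_birds = 8, rng_seed = 17)
  tr2 <- simulate_tracks(cfg2)
  fr2 <- simulate_camera(tr2, cfg2)
  stopifnot(nrow(fr2) == nrow(tr2))    # one frame per fix
  leg <- ifelse(is.na(tr2$leg_true), "outbound", tr2$leg_true)
  for (s in c("travel", "forage", "rest")) {
    for (l in c("outbound", "inbound")) {
      i <- tr2$state_true == s & leg == l & !is.na(tr2$leg_true)
      n <- sum(i)
      if (n < 300) next
      p <- cfg2$social_p[s, l]
      expect_lt(abs(mean(fr2$social[i]) - p),
                3 * sqrt(p * (1 - p) / n))
    }
  }
})

test_that("camera dropout removes trailing frames only", {
  cfg <- sim_config(n_birds = 2, trip_fixes = 80, rng_seed = 8)
  tr <- simulate_tracks(cfg)
  full <- simulate_camera(tr, cfg)
  cut <- simulate_camera(tr, cfg, dropout = 0.3)
  for (b in unique(tr$bird_id)) {
    fb <- full[full$bird_id == b, ]
    cb <- cut[cut$bird_id == b, ]
    expect_equal(nrow(cb), ceiling(nrow(fb) * 0.7))
    expect_identical(cb$timestamp, fb$timestamp[seq_len(nrow(cb))])
  }
})

test_that("flock sizes are positive, reproducible, and larger inbound", {
  cfg <- sim_config(rng_seed = 31)
  fl <- simulate_flocks(cfg)
  expect_identical(fl, simulate_flocks(cfg))
  expect_true(all(fl$size >= 1))
  expect_equal(as.vector(table(fl$direction)),
               as.vector(cfg$n_flock_obs))
  ft <- flock_tests(fl)
  expect_lt(ft$rank$value, 0)  # departing flocks stochastically smaller
  expect_gt(ft$mean_flock_inbound, ft$mean_flock_outbound)
})
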