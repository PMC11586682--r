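t0 <- as.POSIXct("2011-07-01 10:00:00", tz = "UTC")

test_that("step metrics recover speed and turning geometry", {
  trip <- data.frame(timestamp = t0 + 0:3 * 60,
                     lon = 0.01 * (0:3), lat = 0)
  sm <- step_metrics(trip)
  # 0.01 deg of longitude at the equator over 60 s
  expect_equal(sm$speed_ms, rep(1111.9493 / 60, 4), tolerance = 1e-4)
  expect_equal(sm$turn_deg, rep(0, 4), tolerance = 1e-9)

  back <- data.frame(timestamp = t0 + 0:2 * 60,
                     lon = c(0, 0.01, 0), lat = 0)
  expect_equal(step_metrics(back)$turn_deg[2], 180, tolerance = 1e-9)
  expect_error(step_metrics(trip[1:2, ]), "3 fixes")
})

test_that("state classification applies the speed/turn thresholds", {
  expect_equal(as.character(classify_states(1, 10)), "rest")
  expect_equal(as.character(classify_states(15, 5)), "travel")
  expect_equal(as.character(classify_states(15, 90)), "forage")
  expect_equal(as.character(classify_states(5, 5)), "forage")
  expect_error(classify_states(1, 1, v_rest = 10, v_travel = 2), "v_rest")

  # monotonicity: raising v_rest never moves a fix out of rest
  set.seed(2)
  spd <- runif(500, 0, 20); trn <- runif(500, 0, 180)
  lo <- classify_states(spd, trn, v_rest = 2)
  hi <- classify_states(spd, trn, v_rest = 4)
  expect_true(all(which(lo == "rest") %in% which(hi == "rest")))
})

test_that("classification recovers the simulator's latent states", {
  cfg <- sim_config(n_birds = 2, rng_seed = 6)
  tr <- simulate_tracks(cfg)
  tr <- tr[!is.na(tr$leg_true), ]
  tr <- do.call(rbind, lapply(split(tr, tr$bird_id), step_metrics))
  got <- classify_states(tr$speed_ms, tr$turn_deg)
  expect_gt(mean(as.character(got) == tr$state_true), 0.75)
})

test_that("camera joining respects the half-interval window", {
  fixes <- data.frame(bird_id = "B1", timestamp = t0 + 0:9 * 60,
                      leg = factor(rep(c("outbound", "inbound"), each = 5),
                                   levels = c("outbound", "inbound")))
  frames <- data.frame(bird_id = "B1",
                       timestamp = c(t0 + 10, t0 + 60 + 45, t0 + 2 * 60),
                       social = c(TRUE, TRUE, FALSE))
  j <- join_camera(fixes, frames)
  expect_true(j$social[1])        # +10 s matched
  expect_true(is.na(j$social[2])) # +45 s outside the 30-s window
  expect_false(j$social[3])
  cov <- attr(j, "leg_coverage")
  expect_true(all(cov$coverage <= 1))
  expect_length(attr(j, "complete_birds"), 0)  # coverage far from complete
})

test_that("birds with incomplete leg coverage drop from leg-level tables", {
  cfg <- sim_config(n_birds = 4, rng_seed = 15)
  tr <- simulate_tracks(cfg)
  frames <- simulate_camera(tr, cfg)
  # kill the camera halfway for one bird (loses its inbound leg)
  dead <- "B02"
  fb <- frames[frames$bird_id == dead, ]
  frames <- rbind(frames[frames$bird_id != dead, ],
                  fb[seq_len(floor(nrow(fb) / 2)), ])
  tp <- process_tracks(tr[, c("bird_id", "timestamp", "lon", "lat")],
                       cfg$colony)
  fx <- tp$fixes
  fx <- do.call(rbind, lapply(split(fx, fx$trip_id), step_metrics))
  fx$state <- classify_states(fx$speed_ms, fx$turn_deg)
  fx <- join_camera(fx, frames)
  expect_false(dead %in% attr(fx, "complete_birds"))
  pooled <- behaviour_social_table(fx)
  split_tab <- behaviour_social_table(fx, by_leg = TRUE)
  expect_true(dead %in% pooled$bird_id)       # retained in pooled table
  expect_false(dead %in% split_tab$bird_id)   # excluded from leg contrast
})

test_that("behaviour table percentages are internally consistent", {
  fx <- data.frame(bird_id = rep(c("A", "B"), c(40, 60)),
                   state = factor(c(rep("rest", 40),
                                    rep(c("forage", "travel"), 30)),
                                  levels = c("travel", "forage", "rest")),
                   social = FALSE)
  tab <- behaviour_social_table(fx)
  a <- tab[tab$bird_id == "A", ]
  expect_equal(a$pct_fixes_rest, 100)
  expect_equal(a$pct_social_rest, 0)
  expect_true(is.na(a$pct_social_forage))   # no forage fixes for A
  # per-bird state percentages sum to 100
  pct <- as.matrix(tab[, paste0("pct_fixes_", c("travel", "forage", "rest"))])
  expect_equal(rowSums(pct), rep(100, 3), tolerance = 0.1)
  # pooled row equals the fix-weighted mean of the per-bird rows
  tot <- tab[tab$bird_id == "Total", ]
  birds <- tab[tab$bird_id != "Total", ]
  expect_equal(tot$pct_fixes_forage,
               sum(birds$pct_fixes_forage * birds$n) / sum(birds$n))
  expect_equal(tot$n, sum(birds$n))
})

test_that("leg-split tables reproduce the empirical social rates exactly", {
  cfg <- sim_config(n_birds = 8, rng_seed = 23)
  tr <- simulate_tracks(cfg)
  frames <- simulate_camera(tr, cfg)
  fx <- tr[!is.na(tr$leg_true), ]
  fx$state <- factor(fx$state_true, levels = c("travel", "forage", "rest"))
  fx$leg <- factor(fx$leg_true, levels = c("outbound", "inbound"))
  fx <- join_camera(fx, frames)
  tab <- behaviour_social_table(fx, by_leg = TRUE)
  tot <- tab[tab$bird_id == "Total", ]
  # pooled rates equal the directly computed empirical proportions
  for (l in c("outbound", "inbound")) {
    for (s in c("travel", "forage", "rest")) {
      i <- fx$state == s & fx$leg == l & !is.na(fx$social)
      expect_equal(tot[[paste0("pct_social_", s, "_", l)]],
                   100 * mean(fx$social[i]))
      expect_equal(tot[[paste0("pct_fixes_", s, "_", l)]],
                   100 * sum(i) / sum(fx$leg == l & !is.na(fx$social)))
    }
  }
  # leg contrast in commuting sociality has the configured direction
  expect_gt(tot$pct_social_travel_inbound, tot$pct_social_travel_outbound)
})

test_that("spearman rho matches the rank formula and enumeration", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30))$value, 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1))$value, -1)
  # 1 - 6*4 / (4*15) = 0.6
  r <- spearman_rho(1:4, c(2, 1, 4, 3))
  expect_equal(r$value, 0.6)
  expect_equal(r$method, "exact")
  expect_equal(r$p, mean(abs(apply(all_perms(4), 1,
    function(i) cor(1:4, c(2, 1, 4, 3)[i]))) >= 0.6 - 1e-12))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})
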