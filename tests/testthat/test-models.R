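test_that("pearson chi2 matches the closed form on random tables", {
  set.seed(4)
  for (r in 1:1000) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
    got <- pearson_chi2_2x2(tab)$value
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    ref <- sum(tab) * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(got, ref, tolerance = 1e-9)
  }
  expect_equal(pearson_chi2_2x2(matrix(c(10, 20, 30, 60), 2,
                                       byrow = TRUE))$value, 0)
  expect_equal(pearson_chi2_2x2(matrix(c(5, 0, 0, 5), 2))$value, 10)
  expect_error(pearson_chi2_2x2(matrix(c(5, 0, 5, 0), 2)), "margin")
})

test_that("rank z has the documented sign, ties and exact small-sample p", {
  same <- rank_z(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$value, 0)
  expect_equal(same$p, 1)

  sep <- rank_z(c(1, 2, 3), c(4, 5, 6))
  expect_lt(sep$value, 0)          # first sample stochastically smaller
  # exact two-sided p by enumeration of all C(6,3) rank splits
  splits <- combn(6, 3)
  u <- apply(splits, 2, function(i) sum(i) - 6)
  p_exact <- mean(abs(u - 4.5) >= abs(0 - 4.5))
  expect_equal(p_exact, 0.1)
  expect_equal(sep$p, p_exact)

  expect_equal(rank_z(rep(2, 5), rep(2, 4))$value, 0)  # all tied
})

test_that("parsimony selection picks the simplest model in the window", {
  expect_equal(select_parsimonious(100, 4), 1)
  # outside the window: the better model wins regardless of size
  expect_equal(select_parsimonious(c(100, 107), c(9, 2)), 1)
  # inside: fewest parameters, tie broken by AIC
  expect_equal(select_parsimonious(c(100, 104), c(9, 2)), 2)
  expect_equal(select_parsimonious(c(101, 100), c(3, 3)), 2)
})

test_that("published AIC tables select the reported parsimonious models", {
  aic <- ref_depth_duration_aic()
  dep <- aic[aic$response == "depth", ]
  expect_equal(dep$model[select_parsimonious(dep$AIC, dep$n_par)],
               "ColDist + Sex")
  dur <- aic[aic$response == "duration", ]
  expect_equal(dur$model[select_parsimonious(dur$AIC, dur$n_par)], "1")
})

test_that("zero-noise depth data returns the exact generating slope", {
  set.seed(1)
  dt <- data.frame(bird_id = rep(sprintf("B%02d", 1:10), each = 30),
                   colony_dist_km = runif(300, 20, 250))
  dt$depth_m <- 5 + 0.008 * dt$colony_dist_km
  fit <- lme4::lmer(depth_m ~ colony_dist_km + (1 | bird_id), data = dt,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(unname(lme4::fixef(fit)["colony_dist_km"]), 0.008,
               tolerance = 1e-6)
})

test_that("depth model selection table is AIC-consistent and recovers truth", {
  dt <- simulate_dive_table(n_birds = 30, dives_per_bird = 30, seed = 77)
  ms <- fit_depth_model(dt)
  # AIC = 2k - 2 logLik for every candidate
  expect_equal(ms$table$AIC, 2 * ms$table$n_par - 2 * ms$table$logLik,
               tolerance = 1e-6)
  expect_lte(ms$table$AIC[match(ms$selected, ms$table$model)] -
               min(ms$table$AIC), 6)
  expect_true(grepl("ColDist", ms$selected))
  expect_true(grepl("Sex", ms$selected))
  cf <- ms$coef
  sl <- cf[cf$term == "colony_dist_km", ]
  sx <- cf[cf$term == "sexmale", ]
  expect_lt(abs(sl$estimate - 0.008), 2 * sl$se)
  expect_lt(abs(sx$estimate - (-1.272)), 2 * sx$se)
  expect_gte(ms$r2[["conditional"]], ms$r2[["marginal"]])
})

test_that("covariate-free durations select the null model", {
  dt <- simulate_dive_table(n_birds = 30, dives_per_bird = 30, seed = 19)
  ms <- fit_duration_model(dt)
  expect_equal(ms$selected, "1")
})

test_that("the binomial smooth recovers a leg offset and rising halo", {
  set.seed(42)
  n_birds <- 30
  fx <- do.call(rbind, lapply(seq_len(n_birds), function(b) {
    n <- 400
    data.frame(bird_id = sprintf("B%02d", b),
               colony_dist_km = runif(n, 0, 250),
               leg = sample(c("outbound", "inbound"), n, replace = TRUE),
               b0 = rnorm(1, 0, 0.3))
  }))
  eta <- -4 + 0.02 * fx$colony_dist_km - 0.2 * (fx$leg == "inbound") + fx$b0
  fx$dive <- rbinom(nrow(fx), 1, plogis(eta))
  fit <- fit_dive_probability(fx)
  cf <- fit$coef[fit$coef$term == "leginbound", ]
  expect_lt(abs(cf$estimate - (-0.2)), 2 * cf$se)
  # posterior-mean outbound curve rises monotonely with distance
  pr <- fit$pred[fit$pred$leg == "outbound", ]
  expect_true(all(diff(pr$fit) > -1e-8))
  expect_gte(fit$r2[["conditional"]], fit$r2[["marginal"]] - 1e-12)
})

test_that("a flat social generator yields a flat fitted smooth", {
  set.seed(9)
  fx <- data.frame(bird_id = rep(sprintf("B%02d", 1:12), each = 300),
                   colony_dist_km = runif(3600, 0, 200),
                   leg = sample(c("outbound", "inbound"), 3600,
                                replace = TRUE))
  fx$social <- rbinom(3600, 1, 0.15)
  fit <- fit_social_probability(fx)
  # fitted probabilities stay near the generating constant everywhere
  expect_lt(max(abs(fit$pred$fit - 0.15)), 0.05)
  expect_true(all(fit$smooths$edf[grep("colony", fit$smooths$term)] < 3))
})

test_that("mixed-model R2 recovers a known variance partition", {
  set.seed(10)
  nb <- 150; no <- 40
  bird <- rep(seq_len(nb), each = no)
  x <- rnorm(nb * no)
  y <- sqrt(2) * x + rep(rnorm(nb, 0, 1), each = no) + rnorm(nb * no, 0, 1)
  fit <- lme4::lmer(y ~ x + (1 | bird))
  r2 <- r_squared_mixed(fit)
  expect_equal(r2[["marginal"]], 0.5, tolerance = 0.05)
  expect_equal(r2[["conditional"]], 0.75, tolerance = 0.05)

  # zero random-effect variance: marginal equals conditional
  y2 <- sqrt(2) * x + rnorm(nb * no, 0, 1)
  fit2 <- suppressMessages(lme4::lmer(y2 ~ x + (1 | bird),
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  r22 <- r_squared_mixed(fit2)
  expect_equal(r22[["marginal"]], r22[["conditional"]], tolerance = 0.01)

  # zero fixed effects: marginal near zero
  y3 <- rep(rnorm(nb), each = no) + rnorm(nb * no)
  fit3 <- lme4::lmer(y3 ~ 1 + (1 | bird))
  expect_lt(r_squared_mixed(fit3)[["marginal"]], 1e-6)
})

test_that("flock tests wire the contingency and rank statistics together", {
  obs <- rbind(
    data.frame(direction = "outbound",
               size = c(rep(1, 20), rep(2:4, each = 10))),
    data.frame(direction = "inbound",
               size = c(rep(1, 8), rep(c(5, 9, 14), each = 10))))
  ft <- flock_tests(obs)
  expect_equal(unname(ft$contingency["outbound", ]), c(20, 30))
  expect_equal(ft$chi2$df, 1L)
  expect_lt(ft$rank$value, 0)
  expect_gt(ft$mean_flock_inbound, ft$mean_flock_outbound)

  # degenerate all-singleton direction keeps the contingency but no rank z
  ft2 <- flock_tests(data.frame(direction = rep(c("outbound", "inbound"),
                                                each = 5),
                                size = c(rep(1, 5), rep(3, 5))))
  expect_null(ft2$rank)
})
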