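#' Distance-dependent dive-probability model
#'
#' Binomial (logit) generalized additive mixed model of the per-fix dive
#' indicator: a penalized thin-plate smooth of colony distance fitted
#' separately for the outbound and inbound legs, parametric terms for leg,
#' sex and year (factors with a single level in the data are dropped), and a
#' bird-level random intercept (random-effect smooth). Smoothing parameters
#' are selected by REML. Legs with fewer than `min_fixes_smooth` fixes
#' trigger a fallback from by-leg smooths to a single linear distance term,
#' with a message.
#'
#' @param fix_table Data frame with one row per analysed GPS fix: `dive`
#'   (0/1), `colony_dist_km`, `leg`, `sex`, `year`, `bird_id`.
#' @param k Basis dimension of each per-leg smooth (default 10).
#' @param min_fixes_smooth Minimum fixes per leg to fit a smooth.
#' @return A `cpf_fit` object: the fitted `mgcv::gam` model plus coefficient
#'   and smooth-term tables, AIC, log-likelihood, marginal/conditional R2
#'   and a per-leg prediction grid (`pred`: `colony_dist_km`, `leg`, `fit`,
#'   `lo95`, `hi95` on the probability scale, random effect excluded).
#' @export
fit_dive_probability <- function(fix_table, k = 10, min_fixes_smooth = 20) {
  fit_binomial_smooth(fix_table, response = "dive", k = k,
                      min_fixes_smooth = min_fixes_smooth)
}

#' Distance-dependent social-probability model
#'
#' Same contract as [fit_dive_probability()] with the per-fix conspecific
#' flag as the response, fitted to foraging-state fixes of birds with
#' complete camera coverage. Sex/year columns are optional and used when
#' present with more than one level.
#'
#' @param fix_table Data frame with `social` (0/1 or logical),
#'   `colony_dist_km`, `leg`, `bird_id` and optionally `sex`, `year`.
#' @inheritParams fit_dive_probability
#' @return A `cpf_fit` object (see [fit_dive_probability()]).
#' @export
fit_social_probability <- function(fix_table, k = 10, min_fixes_smooth = 20) {
  fit_binomial_smooth(fix_table, response = "social", k = k,
                      min_fixes_smooth = min_fixes_smooth)
}

fit_binomial_smooth <- function(dat, response, k = 10, min_fixes_smooth = 20) {
  need <- c(response, "colony_dist_km", "leg", "bird_id")
  stopifnot(all(need %in% names(dat)))
  dat <- dat[stats::complete.cases(dat[, need]), , drop = FALSE]
  dat$.y <- as.numeric(dat[[response]])
  dat$leg <- factor(dat$leg,
                    levels = intersect(c("outbound", "inbound"),
                                       unique(as.character(dat$leg))))
  dat$bird_id <- factor(dat$bird_id)
  par_terms <- "leg"[nlevels(dat$leg) > 1]
  for (v in c("sex", "year")) {
    if (v %in% names(dat)) {
      dat[[v]] <- factor(dat[[v]])
      if (nlevels(dat[[v]]) > 1) par_terms <- c(par_terms, v)
    }
  }
  leg_n <- table(dat$leg)
  use_smooth <- all(leg_n >= min_fixes_smooth)
  if (!use_smooth)
    message("a leg has fewer than ", min_fixes_smooth,
            " fixes: using a linear distance term instead of by-leg smooths")
  sm <- if (use_smooth && nlevels(dat$leg) > 1) {
    sprintf("s(colony_dist_km, by = leg, k = %d)", k)
  } else if (use_smooth) {
    sprintf("s(colony_dist_km, k = %d)", k)
  } else {
    "colony_dist_km"
  }
  rhs <- paste(c(par_terms, sm, "s(bird_id, bs = 're')"), collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  fit <- mgcv::gam(form, data = dat, family = stats::binomial(),
                   method = "REML")
  sfit <- summary(fit)
  coef_tab <- data.frame(term = rownames(sfit$p.table),
                         estimate = sfit$p.table[, 1],
                         se = sfit$p.table[, 2],
                         z = sfit$p.table[, 3],
                         p = sfit$p.table[, 4], row.names = NULL)
  smooth_tab <- if (!is.null(sfit$s.table))
    data.frame(term = rownames(sfit$s.table),
               edf = sfit$s.table[, 1],
               chi_sq = sfit$s.table[, 3],
               p = sfit$s.table[, 4], row.names = NULL)
  else data.frame()

  pred <- do.call(rbind, lapply(levels(dat$leg), function(l) {
    dl <- dat$colony_dist_km[dat$leg == l]
    if (length(dl) < 2) return(NULL)
    nd <- data.frame(colony_dist_km = seq(min(dl), max(dl), length.out = 100),
                     leg = factor(l, levels = levels(dat$leg)),
                     bird_id = factor(levels(dat$bird_id)[1],
                                      levels = levels(dat$bird_id)))
    for (v in intersect(c("sex", "year"), par_terms))
      nd[[v]] <- factor(levels(dat[[v]])[1], levels = levels(dat[[v]]))
    pr <- mgcv::predict.gam(fit, nd, type = "link", se.fit = TRUE,
                            exclude = "s(bird_id)")
    data.frame(colony_dist_km = nd$colony_dist_km, leg = l,
               fit = stats::plogis(pr$fit),
               lo95 = stats::plogis(pr$fit - 1.96 * pr$se.fit),
               hi95 = stats::plogis(pr$fit + 1.96 * pr$se.fit))
  }))
  structure(list(model = fit, formula = paste(".y ~", rhs),
                 response = response, coef = coef_tab, smooths = smooth_tab,
                 aic = stats::AIC(fit), logLik = as.numeric(stats::logLik(fit)),
                 r2 = r_squared_mixed(fit), pred = pred,
                 meta = list(k = k, criterion = "REML",
                             smooth = use_smooth)),
            class = "cpf_fit")
}

#' @export
print.cpf_fit <- function(x, ...) {
  cat("cpf_fit (", x$response, "):", x$formula, "\n")
  cat("  AIC =", format(x$aic, digits = 6),
      "; mR2 =", round(x$r2[["marginal"]], 3),
      "; cR2 =", round(x$r2[["conditional"]], 3), "\n")
  print(x$coef, digits = 3)
  if (nrow(x$smooths)) print(x$smooths, digits = 3)
  invisible(x)
}

# ---- linear mixed models with AIC candidate set ---------------------------

# singular random-effect fits are expected for near-null candidates; they
# are flagged once at selection time rather than on every candidate fit
quiet_lmer <- function() {
  lme4::lmerControl(check.conv.singular = "ignore")
}

# the additive candidate terms; Time enters as a quadratic pair
lmm_term_sets <- function(dat) {
  terms <- list(ColDist = "colony_dist_km",
                Time = c("tod_h", "I(tod_h^2)"),
                Leg = "leg", Sex = "sex", Year = "year")
  keep <- vapply(names(terms), function(nm) {
    v <- terms[[nm]][1]
    v <- sub("I\\((.*)\\^2\\)", "\\1", v)
    if (!v %in% names(dat)) return(FALSE)
    if (is.numeric(dat[[v]])) stats::sd(dat[[v]]) > 0
    else nlevels(factor(dat[[v]])) > 1
  }, TRUE)
  terms[keep]
}

fit_lmm_set <- function(dat, response) {
  stopifnot(all(c(response, "bird_id") %in% names(dat)))
  for (v in intersect(c("leg", "sex", "year"), names(dat)))
    dat[[v]] <- factor(dat[[v]])
  dat$bird_id <- factor(dat$bird_id)
  terms <- lmm_term_sets(dat)
  nm <- names(terms)
  subsets <- lapply(0:(2^length(nm) - 1), function(b) {
    nm[bitwAnd(b, 2^(seq_along(nm) - 1)) > 0]
  })
  fits <- list(); rows <- list()
  for (ss in subsets) {
    label <- if (length(ss)) paste(ss, collapse = " + ") else "1"
    rhs <- c(unlist(terms[ss], use.names = FALSE), "(1 | bird_id)")
    form <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
    f <- lme4::lmer(form, data = dat, REML = FALSE, control = quiet_lmer())
    ll <- stats::logLik(f)
    fits[[label]] <- f
    rows[[label]] <- data.frame(model = label, n_par = attr(ll, "df"),
                                AIC = stats::AIC(f),
                                logLik = as.numeric(ll))
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab <- tab[order(tab$AIC), ]
  tab$delta <- tab$AIC - min(tab$AIC)
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  list(table = tab[, c("model", "AIC", "delta", "weight", "logLik", "n_par")],
       fits = fits, data = dat, terms = terms, response = response)
}

finish_lmm_selection <- function(set, delta = 6) {
  tab <- set$table
  sel_row <- select_parsimonious(tab$AIC, tab$n_par, delta = delta)
  sel_name <- tab$model[sel_row]
  sel_terms <- if (sel_name == "1") character(0)
               else strsplit(sel_name, " \\+ ")[[1]]
  rhs <- c(unlist(set$terms[sel_terms], use.names = FALSE), "(1 | bird_id)")
  form <- stats::as.formula(paste(set$response, "~",
                                  paste(rhs, collapse = " + ")))
  fit_reml <- lme4::lmer(form, data = set$data, REML = TRUE,
                         control = quiet_lmer())
  if (lme4::isSingular(fit_reml))
    message("singular random-effect fit for selected model (kept)")
  cf <- summary(fit_reml)$coefficients
  coef_tab <- data.frame(term = rownames(cf), estimate = cf[, 1],
                         se = cf[, 2], t = cf[, 3], row.names = NULL)
  # drop-one likelihood-ratio tests of the retained terms (ML fits)
  lrt <- NULL
  if (length(sel_terms)) {
    full_ml <- set$fits[[sel_name]]
    lrt <- do.call(rbind, lapply(sel_terms, function(tm) {
      red <- setdiff(sel_terms, tm)
      red_name <- if (length(red)) paste(red, collapse = " + ") else "1"
      a <- stats::anova(set$fits[[red_name]], full_ml)
      data.frame(term = tm, chi_sq = a$Chisq[2], df = a$Df[2],
                 p = a$`Pr(>Chisq)`[2])
    }))
  }
  structure(list(table = set$table, selected = sel_name, fit = fit_reml,
                 coef = coef_tab, lrt = lrt,
                 r2 = r_squared_mixed(fit_reml),
                 aic = stats::AIC(fit_reml),
                 logLik = as.numeric(stats::logLik(fit_reml)),
                 response = set$response, delta = delta),
            class = "cpf_modsel")
}

#' Dive-depth linear mixed model with AIC-based parsimony selection
#'
#' Fits the full additive candidate set over colony distance, quadratic
#' time of day, leg, sex and year (every subset plus the intercept-only
#' null), each with a bird random intercept, by maximum likelihood for AIC
#' comparison. The most parsimonious model within `delta` AIC of the best
#' (see [select_parsimonious()]) is refitted by REML for reported
#' coefficients, and the retained terms are tested by drop-one
#' likelihood-ratio tests.
#'
#' @param dive_table Data frame with one row per georeferenced dive:
#'   `depth_m` (or `duration_s` for [fit_duration_model()]),
#'   `colony_dist_km`, `leg`, `sex`, `year`, `tod_h` (decimal hour of day),
#'   `bird_id`. Covariate columns that are absent or constant are dropped
#'   from the candidate set.
#' @param delta AIC window of the parsimony rule (default 6).
#' @return A `cpf_modsel` object: `table` (AIC ranking with delta and
#'   Akaike weights), `selected`, the REML `fit`, `coef`, `lrt`,
#'   marginal/conditional `r2`.
#' @export
fit_depth_model <- function(dive_table, delta = 6) {
  finish_lmm_selection(fit_lmm_set(dive_table, "depth_m"), delta)
}

#' @rdname fit_depth_model
#' @export
fit_duration_model <- function(dive_table, delta = 6) {
  finish_lmm_selection(fit_lmm_set(dive_table, "duration_s"), delta)
}

#' @export
print.cpf_modsel <- function(x, ...) {
  cat("cpf_modsel (", x$response, "): selected ", x$response, " ~ ",
      x$selected, " + (1|bird_id)\n", sep = "")
  print(utils::head(x$table, 8), digits = 5)
  cat("coefficients (REML refit):\n")
  print(x$coef, digits = 4)
  invisible(x)
}

#' Most parsimonious model within an AIC window
#'
#' Among models whose AIC lies within `delta` of the minimum, returns the
#' one with the fewest estimated parameters (ties broken by lower AIC) —
#' the information-theoretic parsimony rule under which a simpler model is
#' preferred unless a richer one improves AIC by more than `delta`.
#'
#' @param aic Numeric vector of AIC values.
#' @param n_par Number of estimated parameters of each model.
#' @param delta AIC window (default 6).
#' @return Index of the selected model.
#' @export
select_parsimonious <- function(aic, n_par, delta = 6) {
  stopifnot(length(aic) >= 1, length(aic) == length(n_par))
  cand <- which(aic - min(aic) <= delta)
  cand <- cand[order(n_par[cand], aic[cand])]
  cand[1]
}

# ---- simple tests ---------------------------------------------------------

#' Pearson chi-squared test of a 2x2 contingency table
#'
#' Pearson's chi-squared without continuity correction (df = 1), plus the
#' cross-product odds ratio. Used to compare singleton versus flock counts
#' between outbound and inbound colony movements.
#'
#' @param tab 2x2 matrix of non-negative counts with all margins positive.
#' @return A `cpf_test`: `statistic = "pearson_chi2"`, `value`, `df = 1`,
#'   `p`, `n`, `odds_ratio`.
#' @export
pearson_chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = "pearson_chi2",
                 value = as.numeric(ct$statistic),
                 df = 1L, p = ct$p.value, n = sum(tab),
                 odds_ratio = (tab[1, 1] * tab[2, 2]) /
                              (tab[1, 2] * tab[2, 1])),
            class = "cpf_test")
}

#' Rank-sum z test for two samples of flock sizes
#'
#' Mann-Whitney/Wilcoxon rank-sum comparison reported as a normal-deviate
#' `z` with tie correction and continuity correction. The sign convention is
#' that `z < 0` when the first sample is stochastically smaller (e.g.,
#' departing flocks smaller than arriving ones). The p-value is exact
#' (enumeration via the Wilcoxon distribution) for small untied samples and
#' otherwise uses the corrected normal approximation.
#'
#' @param a,b Numeric vectors (each of length >= 2); by convention `a` =
#'   departing/outbound, `b` = arriving/inbound.
#' @return A `cpf_test`: `statistic = "rank_z"`, `value` (z), `p`, `n`.
#' @export
rank_z <- function(a, b) {
  m <- length(a); n <- length(b)
  stopifnot(m >= 2, n >= 2)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  nt <- table(pooled)
  tiecor <- sum(nt^3 - nt)
  N <- m + n
  sig2 <- m * n / 12 * ((N + 1) - tiecor / (N * (N - 1)))
  if (sig2 <= 0 || u == mu) {
    z <- 0; p <- 1
  } else {
    z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sig2)
    p <- if (tiecor == 0 && N <= 50) {
      stats::wilcox.test(a, b, exact = TRUE)$p.value
    } else {
      2 * stats::pnorm(-abs(z))
    }
  }
  structure(list(statistic = "rank_z", value = z, df = NA_integer_,
                 p = p, n = N),
            class = "cpf_test")
}

#' Flock-observation tests
#'
#' From a table of colony departure/arrival observations, builds the 2x2
#' singleton-versus-flock contingency table (rows outbound/inbound) and
#' tests it with [pearson_chi2_2x2()], then compares the sizes of true
#' flocks (size >= 2; singletons excluded) between directions with
#' [rank_z()], outbound first.
#'
#' @param obs Data frame with `direction` (outbound/inbound) and `size`.
#' @return List: `contingency` (the 2x2 table), `chi2`, `rank`, and per-
#'   direction mean flock sizes (`mean_flock_outbound`,
#'   `mean_flock_inbound`).
#' @export
flock_tests <- function(obs) {
  stopifnot(all(c("direction", "size") %in% names(obs)), all(obs$size >= 1))
  dir <- factor(obs$direction, levels = c("outbound", "inbound"))
  tab <- rbind(
    outbound = c(alone = sum(dir == "outbound" & obs$size == 1),
                 flock = sum(dir == "outbound" & obs$size >= 2)),
    inbound = c(alone = sum(dir == "inbound" & obs$size == 1),
                flock = sum(dir == "inbound" & obs$size >= 2)))
  a <- obs$size[dir == "outbound" & obs$size >= 2]
  b <- obs$size[dir == "inbound" & obs$size >= 2]
  rk <- if (length(a) >= 2 && length(b) >= 2) rank_z(a, b) else NULL
  list(contingency = tab, chi2 = pearson_chi2_2x2(tab), rank = rk,
       mean_flock_outbound = mean(a), mean_flock_inbound = mean(b))
}

# ---- variance explained ---------------------------------------------------

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partition R-squared for mixed models: the marginal value is the
#' variance of the fixed-effect predictor over the total (fixed + random
#' intercept + residual), and the conditional value adds the random-effect
#' variance to the numerator. For binomial logit models the residual
#' variance is the latent-logistic `pi^2 / 3`.
#'
#' @param fit A `lme4::lmer` fit, or an `mgcv::gam` fit containing a
#'   random-effect (`bs = "re"`) smooth.
#' @return Named numeric vector `c(marginal, conditional)`.
#' @export
r_squared_mixed <- function(fit) {
  if (inherits(fit, "merMod")) {
    varF <- stats::var(as.vector(
      lme4::getME(fit, "X") %*% lme4::fixef(fit)))
    vc <- lme4::VarCorr(fit)
    varR <- sum(vapply(vc, function(v) sum(diag(v)), 0))
    varE <- stats::sigma(fit)^2
  } else if (inherits(fit, "gam")) {
    re <- vapply(fit$smooth, function(s)
      identical(class(s)[1], "random.effect"), TRUE)
    re_terms <- vapply(fit$smooth[re], function(s) s$label, "")
    lp_fixed <- mgcv::predict.gam(fit, type = "link",
                                  exclude = if (length(re_terms)) re_terms)
    varF <- stats::var(as.vector(lp_fixed))
    utils::capture.output(vcs <- suppressWarnings(mgcv::gam.vcomp(fit)))
    vcs <- if (is.matrix(vcs)) vcs[, 1] else vcs
    varR <- sum(vcs[names(vcs) %in% re_terms]^2)
    varE <- if (stats::family(fit)$family == "binomial") pi^2 / 3
            else fit$sig2
  } else stop("unsupported model class")
  tot <- varF + varR + varE
  if (!is.finite(tot) || tot <= 0) return(c(marginal = NA_real_,
                                            conditional = NA_real_))
  c(marginal = varF / tot, conditional = (varF + varR) / tot)
}
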