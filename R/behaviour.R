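#' Per-fix speed and turning angle
#'
#' Speed of fix *i* is the great-circle distance from fix *i-1* divided by
#' the elapsed time; the turning angle at fix *i* is the absolute difference
#' between the bearings of the incoming and outgoing segments, folded to
#' `[0, 180]` degrees. Endpoints, which lack one neighbour, carry the value
#' of the adjacent fix so that every fix can be classified.
#'
#' @param trip Data frame for a single trip: `timestamp`, `lon`, `lat`
#'   (strictly increasing timestamps, at least 3 fixes for turning angles).
#' @return `trip` with added numeric columns `speed_ms` and `turn_deg`.
#' @export
step_metrics <- function(trip) {
  stopifnot(is.data.frame(trip),
            all(c("timestamp", "lon", "lat") %in% names(trip)))
  n <- nrow(trip)
  if (n < 3L) stop("need at least 3 fixes for turning angles")
  tt <- as.numeric(trip$timestamp)
  dt <- diff(tt)
  if (any(dt <= 0)) stop("non-increasing timestamps in trip")
  p <- cbind(trip$lon, trip$lat)
  seg_km <- hav_km(p[-n, 1], p[-n, 2], p[-1, 1], p[-1, 2])
  spd <- seg_km * 1000 / dt
  brg <- bearing_deg(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
  dtheta <- abs(diff(brg)) %% 360
  turn <- pmin(dtheta, 360 - dtheta)
  trip$speed_ms <- c(spd[1], spd)
  trip$turn_deg <- c(turn[1], turn, turn[length(turn)])
  trip
}

#' Classify behavioural states from speed and turning angle
#'
#' Threshold rule over per-fix movement metrics: below `v_rest` the bird is
#' resting (drifting on the water); at or above `v_travel` with a turning
#' angle below `turn_forage` it is travelling in directed flight; anything
#' else — intermediate speeds, or fast but tortuous flight — is classed as
#' foraging (area-restricted search).
#'
#' @param speed_ms,turn_deg Numeric vectors of per-fix speed (m/s) and
#'   turning angle (degrees in `[0, 180]`).
#' @param v_rest,v_travel Speed thresholds (m/s), `v_rest < v_travel`.
#' @param turn_forage Turning-angle threshold (degrees).
#' @return Factor with levels `travel`, `forage`, `rest`.
#' @export
classify_states <- function(speed_ms, turn_deg,
                            v_rest = 2, v_travel = 10, turn_forage = 45) {
  if (!(v_rest < v_travel)) stop("need v_rest < v_travel")
  if (turn_forage <= 0) stop("turn_forage must be positive")
  out <- ifelse(speed_ms < v_rest, "rest",
                ifelse(speed_ms >= v_travel & turn_deg < turn_forage,
                       "travel", "forage"))
  factor(out, levels = states())
}

#' Join camera frames to GPS fixes
#'
#' Matches each fix to the nearest camera frame of the same bird within
#' `window_s` seconds (half the nominal 1-min interval by default). Fixes
#' without a frame in the window get `social = NA` — absence of a frame is
#' missing data, not absence of conspecifics. Per-bird, per-leg frame
#' coverage is recorded so that birds whose camera died mid-trip can be
#' excluded from leg-level contrasts while remaining in pooled summaries.
#'
#' @param fixes Fix data frame with `bird_id`, `timestamp` and (for coverage
#'   accounting) `leg`.
#' @param frames Camera frames: `bird_id`, `timestamp`, `social` (logical).
#' @param window_s Matching half-window in seconds (default 30).
#' @param coverage_min Minimum fraction of a leg's fixes with a matched
#'   frame for that bird-leg to count as complete (default 0.95).
#' @return `fixes` with an added `social` column; the attribute
#'   `"leg_coverage"` holds a data frame `bird_id`, `leg`, `n_fixes`,
#'   `coverage`, `complete`, and `"complete_birds"` the ids of birds whose
#'   every leg is complete.
#' @export
join_camera <- function(fixes, frames, window_s = 30, coverage_min = 0.95) {
  stopifnot(all(c("bird_id", "timestamp") %in% names(fixes)),
            all(c("bird_id", "timestamp", "social") %in% names(frames)))
  fixes$social <- NA
  for (b in unique(fixes$bird_id)) {
    fi <- which(fixes$bird_id == b)
    fr <- frames[frames$bird_id == b, , drop = FALSE]
    if (nrow(fr) == 0L) next
    ft <- as.numeric(fr$timestamp)
    o <- order(ft); ft <- ft[o]; fr <- fr[o, , drop = FALSE]
    ts <- as.numeric(fixes$timestamp[fi])
    lo <- pmin(pmax(findInterval(ts, ft), 1L), length(ft))
    hi <- pmin(lo + 1L, length(ft))
    j <- ifelse(abs(ft[lo] - ts) <= abs(ft[hi] - ts), lo, hi)
    ok <- abs(ft[j] - ts) <= window_s
    fixes$social[fi[ok]] <- fr$social[j[ok]]
  }
  if ("leg" %in% names(fixes)) {
    cov <- stats::aggregate(!is.na(fixes$social),
                            by = list(bird_id = fixes$bird_id, leg = fixes$leg),
                            FUN = mean)
    nfx <- stats::aggregate(rep(1L, nrow(fixes)),
                            by = list(bird_id = fixes$bird_id, leg = fixes$leg),
                            FUN = sum)
    cov <- data.frame(bird_id = cov$bird_id, leg = cov$leg,
                      n_fixes = nfx$x, coverage = cov$x,
                      complete = cov$x >= coverage_min)
    attr(fixes, "leg_coverage") <- cov
    ok_birds <- tapply(cov$complete, cov$bird_id, all)
    attr(fixes, "complete_birds") <- names(ok_birds)[ok_birds]
  }
  fixes
}

#' Behaviour-by-sociality summary table
#'
#' Per-bird (plus a pooled `Total` row) percentages of fixes in each
#' behavioural state and, within each state, the percentage of fixes with a
#' conspecific in frame. The denominator is the set of fixes with a matched
#' camera frame, so GPS-only periods do not dilute the sociality rates.
#' With `by_leg = TRUE` the table is split into outbound and inbound
#' columns, and only birds with complete camera coverage on every leg (see
#' [join_camera()]) are included.
#'
#' @param fixes Fixes with `bird_id`, `state`, `social` (logical, `NA` =
#'   no frame) and, for `by_leg`, `leg`; typically the output of
#'   [join_camera()].
#' @param by_leg Split by outbound/inbound leg?
#' @return Data frame with one row per bird plus `Total`: for each state
#'   (and leg), `pct_fixes_*` and `pct_social_*` columns and the fix count
#'   `n`. States with no fixes yield `NA` social percentages.
#' @export
behaviour_social_table <- function(fixes, by_leg = FALSE) {
  stopifnot(all(c("bird_id", "state", "social") %in% names(fixes)))
  f <- fixes[!is.na(fixes$social), , drop = FALSE]
  if (by_leg) {
    stopifnot("leg" %in% names(f))
    keep <- attr(fixes, "complete_birds")
    if (!is.null(keep)) f <- f[f$bird_id %in% keep, , drop = FALSE]
  }
  cells <- function(g) {
    n <- nrow(g)
    row <- list(n = n)
    for (s in states()) {
      gs <- g[g$state == s, , drop = FALSE]
      row[[paste0("pct_fixes_", s)]] <- if (n) 100 * nrow(gs) / n else NA_real_
      row[[paste0("pct_social_", s)]] <-
        if (nrow(gs)) 100 * mean(gs$social) else NA_real_
    }
    as.data.frame(row)
  }
  one_block <- function(ff) {
    birds <- lapply(split(ff, ff$bird_id), cells)
    out <- do.call(rbind, c(birds, make.row.names = FALSE))
    out <- cbind(bird_id = names(birds), out)
    tot <- cells(ff); tot <- cbind(bird_id = "Total", tot)
    rbind(out, tot)
  }
  if (!by_leg) return(one_block(f))
  legs <- lapply(c("outbound", "inbound"), function(l) {
    blk <- one_block(f[f$leg == l, , drop = FALSE])
    names(blk)[-1] <- paste0(names(blk)[-1], "_", l)
    blk
  })
  merge(legs[[1]], legs[[2]], by = "bird_id", all = TRUE, sort = FALSE)
}

#' Spearman rank correlation with a permutation p-value
#'
#' Spearman's rho on average-ranked data (ties get mean ranks). The
#' two-sided p-value is computed by exact enumeration of all `n!`
#' permutations for `n <= 8`, and by Monte-Carlo permutation (10,000 draws)
#' for larger samples — appropriate at the small per-bird sample sizes of
#' camera studies, where large-sample approximations are unreliable.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param n_perm Monte-Carlo permutations when `n > 8`.
#' @return List of class `cpf_test`: `statistic = "spearman"`, `value`
#'   (rho), `p`, `n`, `method` ("exact" or "montecarlo").
#' @export
spearman_rho <- function(x, y, n_perm = 10000) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    pm <- all_perms(n)
    rhos <- apply(pm, 1L, function(i) stats::cor(rx, ry[i]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    rhos <- replicate(n_perm, stats::cor(rx, sample(ry)))
    p <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (n_perm + 1)
    method <- "montecarlo"
  }
  structure(list(statistic = "spearman", value = rho, df = NA_integer_,
                 p = p, n = n, method = method),
            class = "cpf_test")
}

# all permutations of 1..n as an n! x n matrix
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.cpf_test <- function(x, ...) {
  cat(x$statistic, ": value =", format(x$value, digits = 4),
      if (!is.na(x$df)) paste(", df =", x$df) else "",
      ", p =", format.pval(x$p, digits = 3), ", n =", x$n, "\n")
  invisible(x)
}
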