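#' Reference values from a published gannet biologging study
#'
#' Small reference tables transcribed from a published study of breeding
#' northern gannets at a large Celtic Sea colony, used as worked-example
#' inputs and as fixed test cases for the statistical layer. They are data,
#' not fitted output of this package.
#'
#' `ref_social_percentages()` returns the per-bird behaviour/sociality
#' percentages for the eight camera birds (percent of fixes per state,
#' percent of those fixes with a conspecific in frame, and total fixes).
#'
#' @return A data frame; see Details.
#' @export
ref_social_percentages <- function() {
  data.frame(
    bird_id = c("G145", "G147", "G149", "G150",
                "G151", "G152", "G153", "G156"),
    pct_fixes_forage = c(21.8, 22.9, 26.3, 10.9, 6.7, 9.8, 21.2, 15.8),
    pct_social_forage = c(36, 33.3, 42.9, 13.4, 17.4, 16.9, 7.2, 21.8),
    pct_fixes_travel = c(36.5, 11.9, 24.1, 17.5, 20.9, 22.6, 17.9, 8.5),
    pct_social_travel = c(14.9, 20.5, 18.75, 26.3, 15.7, 26.8, 6.1, 31.2),
    pct_fixes_rest = c(41.6, 65.2, 49.6, 71.6, 72.4, 67.6, 60.8, 75.7),
    pct_social_rest = c(10.9, 7, 12.1, 4.49, 0.8, 1.1, 8.2, 4.5),
    n = c(550L, 328L, 133L, 1585L, 1031L, 1324L, 1643L, 901L))
}

#' @describeIn ref_social_percentages AIC rankings of the published
#'   dive-depth and dive-duration candidate LMMs (response, model label,
#'   AIC, log-likelihood and the number of estimated parameters: fixed
#'   coefficients plus random-intercept and residual variances; the
#'   time-of-day term is quadratic, hence two coefficients).
#' @export
ref_depth_duration_aic <- function() {
  data.frame(
    response = c(rep("depth", 7), rep("duration", 5)),
    model = c("ColDist + Leg + Sex + Year", "ColDist + Sex + Year",
              "ColDist + Leg + Sex", "ColDist + Sex",
              "ColDist + Time + Leg + Sex + Year",
              "ColDist + Time + Leg + Sex", "1",
              "Year", "Leg + Year", "1", "Leg", "ColDist + Year"),
    AIC = c(6109.3, 6110.1, 6110.5, 6111.4, 6112.6, 6113.7, 6141.0,
            8270.7, 8271.0, 8271.1, 8271.4, 8276.4),
    logLik = c(-3047.625, -3049.070, -3049.234, -3050.725, -3048.322,
               -3049.837, -3067.476,
               -4131.344, -4130.495, -4132.530, -4131.692, -4133.186),
    n_par = c(7L, 6L, 6L, 5L, 9L, 8L, 3L,
              4L, 5L, 3L, 4L, 5L))
}

#' @describeIn ref_social_percentages The 2x2 singleton/flock contingency
#'   table of colony movement observations (295 outbound units, 49% alone;
#'   209 inbound units, 31.6% alone).
#' @export
ref_flock_counts <- function() {
  matrix(c(145L, 150L,
           66L, 143L),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("outbound", "inbound"), c("alone", "flock")))
}
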