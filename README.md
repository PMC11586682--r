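# cpforage

Central-place foraging analysis of colonial seabird biologging data.

Breeding seabirds such as northern gannets (*Morus bassanus*) are
central-place foragers: every feeding trip starts and ends at the colony.
Around large colonies, intraspecific competition is expected to deplete or
disturb prey — *Ashmole's halo* — pushing feeding activity away from the
colony, concentrating birds at the halo's edge, and thereby creating
opportunities for social foraging and flocking on the commute home.
`cpforage` implements the full analysis chain used to test these ideas with
simultaneous GPS, time-depth-recorder (TDR), bird-borne-camera and
colony-watch data, plus a synthetic data generator so the entire pipeline is
testable end to end without field data.

The pipeline:

* **Track processing** — civil-twilight night filtering (solar elevation ≥
  −6° via a NOAA-style ephemeris), splitting tracks into foraging trips
  around a 2-km colony buffer, completeness flagging, natural cubic-spline
  interpolation of fixes to 1 s, and outbound/inbound leg assignment
  relative to the distal point (the fix furthest from the colony).
* **Dive detection** — dives are maximal runs of depth strictly > 1.5 m
  (continuous 1-Hz dialect) or depth-filtered bursts (event-triggered 10-Hz
  dialect); each dive gets a duration and maximum depth and is georeferenced
  to the nearest 1-s track point (mismatches > 1 s excluded).
* **Behaviour & sociality** — per-fix speed/turning-angle metrics,
  threshold classification into travel / forage (area-restricted search) /
  rest, camera-frame joining, behaviour-by-sociality percentage tables and
  Spearman rank-consistency tests with exact permutation p-values.
* **Spatial summaries** — kernel utilization distributions (UD) of dive
  locations on a 1-km azimuthal-equidistant grid with a 10-km isotropic
  Gaussian bandwidth, cumulative-mass contours (the 50% UD is the core
  area), and 5-km distance-binned dive histograms on the colony and
  distal-signed axes.
* **Models & tests** — binomial GAMMs of dive and social probability with
  per-leg smooths of colony distance,

  `logit P(dive) = s_leg(d) + leg + sex + year + b_bird,  b_bird ~ N(0, σ²)`,

  linear mixed models of dive depth and duration over the additive
  candidate set {ColDist, Time², Leg, Sex, Year}, ΔAIC ≤ 6 parsimony
  selection with drop-one likelihood-ratio tests, Nakagawa
  marginal/conditional R², Pearson χ² flock contingency tests and the
  tie-corrected Mann–Whitney rank z for flock sizes.
* **Synthetic data** — a three-state correlated random walk from the colony
  with a trip-budget-induced distal point; dives only at forage fixes with
  `P(dive) = plogis(β₀ + β₁·d)` (the halo), depth `α + 0.008·d − 1.272·male
  + ε`; camera detections with behaviour- and leg-dependent rates; and
  singleton/flock mixtures for departures and arrivals. All streams come
  with ground truth for recovery testing.

## Worked example

```r
library(cpforage)

cfg <- sim_config(n_birds = 12, rng_seed = 404)  # halo: logit p = -4 + 0.02 d
pp  <- sim_pipeline(cfg)   # simulate -> clean -> detect -> georeference

pp$trips
#> cpf_trips: 11 trips ( 11 complete ), 9178 out-of-buffer fixes

h <- bin_by_distance(pp$dive_table)
h$bin_lo[which.max(h$count)]
#> [1] 130            # modal 5-km dive bin sits far offshore
mean(pp$dive_table$colony_dist_km < 25)
#> [1] 0.0198         # almost no diving near the colony: the halo

fit_dive_probability(pp$fix_table)$smooths
#>                            term     edf   chi_sq     p
#> 1 s(colony_dist_km):legoutbound 2.56927 71.41314 0.000
#> 2  s(colony_dist_km):leginbound 1.28694 63.93800 0.000
#> 3                    s(bird_id) 0.00237  0.00118 0.853

fit_depth_model(pp$dive_table)
#> cpf_modsel (depth_m): selected depth_m ~ ColDist + Sex + (1|bird_id)
#>             term  estimate       se      t
#> 1    (Intercept)  5.957731 0.350671 16.990
#> 2 colony_dist_km  0.009134 0.002518  3.628
#> 3        sexmale -1.335981 0.221836 -6.022
```

The depth model recovers the generating coefficients (0.008 m/km distance
slope, −1.272 m male offset) within its standard errors, and the ΔAIC-6
parsimony rule lands on the distance + sex structure. Flock observations
follow the same pattern as colony watches:

```r
ft <- flock_tests(simulate_flocks(cfg))
ft$chi2
#> pearson_chi2 : value = 9.407 , df = 1 , p = 0.00216 , n = 504
ft$rank
#> rank_z : value = -9.395 , p = <2e-16 , n = 285   # departing flocks smaller
```

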