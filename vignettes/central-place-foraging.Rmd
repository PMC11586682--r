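---
title: "Methods: central-place foraging analysis of seabird biologging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: central-place foraging analysis of seabird biologging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpforage)
```

## The scientific problem

Colonially breeding seabirds feed from a fixed central place, so
density-dependent competition should deplete or disturb prey in a zone
around the colony — Ashmole's halo. If a halo exists, diving should be rare
near the colony and concentrated towards the distal ends of foraging trips;
birds aggregating at the halo's edge then have more opportunities for
social foraging (local enhancement) and for flocking on the inbound
commute. `cpforage` packages the full analysis chain needed to examine
these predictions from four simultaneously collected data streams: GPS
tracks, time-depth-recorder (TDR) pressure series, bird-borne camera
frames, and colony flock watches.

Because real deployments are external data, the package ships a
first-class synthetic generator with the same statistical structure, and
every stage is validated by recovering the generator's known parameters.

## Track processing

**Night filtering.** Seabirds typically raft on the water at night, so
fixes between the end of civil dusk and the start of civil dawn are
removed. Civil twilight is operationalised per fix as geometric solar
elevation ≥ −6°, computed at the fix's own position and time with the NOAA
low-accuracy solar ephemeris (truncated Meeus series; position error well
under 0.2°, i.e. under a minute of twilight timing). No refraction
correction is applied — at the −6° threshold refraction shifts timing by
under two minutes, far below the 1-min fix interval's resolution. The
filter is idempotent.

**Trip splitting.** Within 2 km of the colony birds bathe and raft rather
than forage, so a configurable 2-km buffer is excised: a trip is a maximal
run of consecutive fixes beyond the buffer, and the buffer fixes themselves
are discarded during splitting (the buffer's timing relative to splitting
is a package convention; both orders give identical trips for this
definition). A trip is *complete* only when bracketed by in-buffer fixes on
both sides — the bird was seen leaving the colony and returning. Trips
truncated by deployment start or battery death are flagged and excluded
from analysis, which is what "complete foraging trip" means everywhere in
the package.

**Leg assignment.** The distal point is the fix with maximal great-circle
colony distance; ties are broken by the *earliest* such fix, a
deterministic, order-preserving rule. Fixes at or before the distal point
are outbound, later ones inbound, so every analysed fix has exactly one
leg and all outbound fixes precede all inbound ones. The signed distal
axis is negative outbound and positive inbound, zero at the distal fix.

**Interpolation.** For dive georeferencing, lon(t) and lat(t) are fitted
independently with natural cubic splines and evaluated on a 1-s grid;
original fixes are reproduced exactly at their own timestamps. Fitting in
geographic degrees rather than a projection is a deliberate convention:
over trip scales (< 600 km) the induced error is far below GPS error.
Trips with fewer than four fixes fall back to linear interpolation, with a
message. All distances use the haversine formula on a sphere of radius
6371.0 km; geodesic-ellipsoid refinements change distances by ~0.3%, well
below the positional noise of 1-min seabird GPS.

## Dive detection and georeferencing

A dive is a submergence deeper than 1.5 m; shallower excursions are
bathing and other sub-surface non-foraging behaviour. The threshold is
strict (`depth > 1.5`), so a sample at exactly 1.5 m is surface behaviour
and splits a run. Two logger dialects are handled:

* *continuous 1 Hz*: a dive is a maximal run of consecutive samples above
  threshold; duration is the run's span **plus one sampling interval**, so
  a single-sample dive lasts one interval rather than 0 s — the depth
  exceeded threshold throughout that interval. Maximum depth is the run
  maximum.
* *event 10 Hz*: the logger records only during submergence, so each burst
  (gap > 1 s to the next) is a candidate event, retained when its maximum
  depth exceeds threshold.

No zero-offset (surface-drift) correction is applied by default; the
reader leaves a hook for a per-day median-surface correction. Detection is
cross-checked in the test suite against an independent brute-force scan on
hundreds of random traces, and against generator ground truth (exact
recovery at zero measurement noise).

Each dive is assigned to the 1-s interpolated track point nearest its
start time; a mismatch of more than 1 s (typically a dead GPS battery)
excludes the dive, and |Δt| = 1 s exactly is still accepted. Matched dives
inherit the point's position, colony distance and leg.

## Behaviour and sociality

Speed is the great-circle step length over elapsed time; the turning angle
is the absolute bearing change folded to [0°, 180°]; endpoints carry their
neighbour's value. States follow a threshold rule: rest below `v_rest`,
travel at or above `v_travel` with turning below `turn_forage`, otherwise
forage (area-restricted search — slow or tortuous flight). The defaults
(`v_rest` = 2 m/s, `v_travel` = 10 m/s, `turn_forage` = 45°) are
configurable and recorded in output metadata; `v_rest` is above zero
because drift on the water produces non-zero over-ground speed. Raising
`v_rest` can only move fixes *into* rest, a monotonicity property the test
suite asserts.

Camera frames are joined to fixes of the same bird within ±30 s — half the
nominal 1-min interval, so every frame can match at most one fix
nominally. A fix without a frame gets a *missing* social flag, never
`FALSE`: an off camera is not evidence of solitude. Per-bird, per-leg
frame coverage is tracked; birds below 95% coverage on any leg are
excluded from leg-split tables (their camera died mid-trip) while staying
in pooled tables. Sociality tables report, per bird and pooled, the
percentage of matched fixes in each state and the percentage of those that
contain a conspecific.

Rank consistency of per-bird sociality across behaviours uses Spearman's
rho on average ranks with a permutation p-value — exact enumeration of all
n! permutations for n ≤ 8 (the camera sample sizes in question), Monte
Carlo above. Large-sample approximations are not trustworthy at n = 8.

## Spatial summaries

The utilization distribution of dive locations is a fixed-bandwidth kernel
density estimate on a regular grid in an azimuthal-equidistant projection
centred on the colony — the projection in which "a 10-km bandwidth on a
1-km grid" is exactly true in kilometres in every direction from the
colony. The kernel is an isotropic bivariate Gaussian with sd = *h* (the
common fixed-*h* choice in home-range analysis); the grid pads ≥ 4*h*
beyond the point cloud (truncation error < 10⁻⁴ of a kernel's mass) and
cell masses are normalised to sum to one.

Contours are *cumulative-mass* (volume) isopleths: cells are accumulated
in decreasing density order until the level is reached, so the 50% UD is
the smallest cell set holding half the mass. For a single point the 50%
region is a disc of radius `h √(2 ln 2) ≈ 1.1774 h`, which the tests check
to within one cell.

Distance histograms use half-open `[5k, 5(k+1))` km bins. On the signed
distal axis the distal dive itself (0 km) falls in the first non-negative
bin — a documented, configurable convention matching the half-open rule.

## Models and tests

**Dive / social probability.** The per-fix binary response is modelled
with a binomial (logit) GAMM: a penalized thin-plate smooth of colony
distance *by leg* (basis dimension k = 10 per leg), parametric leg, sex
and year terms, and a bird random intercept fitted as a random-effect
smooth. Smoothing parameters are selected by REML (recorded in the fit's
metadata); the penalized fit is delegated to `mgcv`, while model assembly,
the prediction grid and the pointwise 95% intervals (random effect
excluded) are this package's contract. Factors with one observed level
are dropped; a leg with fewer than 20 fixes downgrades the smooth to a
linear distance term, with a message.

**Depth and duration.** Because fitted smooths for depth and duration are
essentially linear, these responses use linear mixed models. The candidate
set is every additive subset of {colony distance, quadratic time of day,
leg, sex, year} plus the null, each with a bird random intercept — 32
models, fitted by ML for AIC comparability. The *most parsimonious* model
is the one with fewest estimated parameters among those within ΔAIC ≤ 6 of
the best (ties → lower AIC): a richer model must buy its extra parameters
with a ≥ 6-unit AIC improvement. The selected model is refitted by REML
for reported coefficients, retained terms are tested by drop-one
likelihood-ratio tests on the ML fits, and singular random-effect fits are
flagged but kept. The quadratic time term enters and leaves the candidate
set as a unit.

**Variance explained.** Marginal R² is var(fixed predictor)/total and
conditional R² adds the random-intercept variance, with the
distribution-specific residual variance in the denominator — σ² for
Gaussian fits, π²/3 (latent logistic) for binomial logit fits. Conditional
R² ≥ marginal R² by construction.

**Flock tests.** Colony watches yield movement units (singletons or
flocks) per direction. Singletons-versus-flocks across directions is a
Pearson χ² on the 2×2 table *without* continuity correction (the
convention under which the package's fixed 2×2 test case reproduces its
reference value exactly). Flock sizes (≥ 2 only; singletons are not
flocks) are compared with a Mann–Whitney rank-sum z with tie and
continuity corrections, negative when the first (departing) sample is
stochastically smaller. The published analysis this layer mirrors does not
name its z statistic; the rank-sum z is the standard nonparametric choice
and is documented as such. Exact p-values are used for small untied
samples.

## The synthetic generator

`sim_config()` holds every generating parameter; all generators are pure
functions of the configuration, with per-stream child seeds derived
deterministically from one master seed, and they emit complete ground
truth (latent state, true leg, true dives, true social flags).

*Movement* is a three-state (travel/forage/rest) first-order correlated
random walk: Markov state transitions per fix, Gaussian speeds truncated
at zero (defaults 14, 4, 0.3 m/s — commuting flight, area-restricted
search, drift), wrapped-Cauchy turning angles (concentrations 0.95, 0.3,
0 — straight, tortuous, undirected). Trips are closed by construction:
travel-state headings carry a weak outward bias during the outbound phase
(directed commuting), and after a trip-duration budget (`trip_fixes`,
default 480 one-minute fixes ≈ 8 h outbound, ≈ 16-h trips) a homing bias
pulls headings back to the colony. The distal point is therefore *induced*
by the budget, not imposed, so downstream leg assignment is non-circular.
The budget was set so trips reach distal points of roughly 150–230 km, the
spatial scale over which the halo pattern of interest plays out; July
dates at 51.7° N give realistic breeding-season day lengths for the
twilight filter.

*Dives* occur only at forage-state fixes with probability
`plogis(halo_beta0 + halo_beta1 · d)` — the halo, defaults −4 + 0.02/km —
and maximum depth `depth_alpha + 0.008·d − 1.272·male + N(0, 2 m)`
truncated above 1.51 m so every simulated dive is detectable
(`depth_alpha` = 6 m, a realistic shallow plunge-dive baseline). Durations
are log-normal (median 12 s) and independent of every covariate, so the
duration model's correct answer is the null. The pressure trace is a
half-sine profile peaking exactly at the true maximum depth, emitted
either as a continuous 1-Hz series or as 10-Hz event bursts.

*Cameras* produce one frame per fix with conspecific probability indexed
by (state, leg); the defaults encode inbound-commuting sociality ≈ 25%
versus outbound ≈ 7%, with foraging intermediate and resting low, the
qualitative pattern the leg-split tables should recover. A dropout
fraction can truncate a bird's frames to emulate battery death.

*Flocks* are singleton/flock mixtures per direction: singleton
probabilities 0.49 (outbound) and 0.316 (inbound), flock sizes
`2 + NB(mu, size)` with means 3.16 and 8.85 — so arriving units are both
more often flocked and larger, the pattern the contingency and rank tests
detect.

The recovery generator `simulate_dive_table()` bypasses the movement model
entirely (uniform 20–250 km distances, Gaussian bird intercepts of sd 1 m,
*untruncated* Gaussian depths) so that mixed-model estimates can be
compared to generating coefficients without truncation bias; the 1.51-m
truncation applies only to the pressure-trace generator, where
detectability is the point.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about field data: GPS position error and irregular fix
gaps; prey-field dynamics (the halo is imposed as a logistic intensity,
not emergent from depletion); spatial and temporal autocorrelation of
dives beyond that induced by the movement states; camera misclassification;
tidal and weather effects; multi-day trips with overnight gaps; and any
between-colony variation.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use desk-scale sizes chosen as
the package's own test conditions: 2–12 birds for pipeline round-trips,
500 random traces for the detector/brute-force equivalence, 50 replicates
of 40 birds × ~35 dives for coefficient recovery (the recovered distance
slope and sex offset are required to lie within 2 SE of truth in ≥ 90% of
replicates, with replicate means within 10%), and 50 replicates for the
null-duration selection rate (≥ 80%). Tolerances follow from the
arithmetic being tested: exact identities at 10⁻⁶–10⁻⁹, Monte-Carlo
properties at 3 binomial SE under fixed seeds, UD mass at 10⁻⁶ of unity.
Degenerate inputs are defined rather than left to chance: empty fix or
sample sets return empty results; a rest-only transition matrix yields
zero complete trips; constant vectors make Spearman's rho an error, and
fully tied samples give z = 0, p = 1.

## Known limitations

* The behaviour classifier is a fixed-threshold rule, not an HMM; states
  near the thresholds are uncertain, and the defaults (2 / 10 m/s, 45°)
  must be tuned per species. They are logged with every output.
* The binomial GAMM treats fixes as conditionally independent given the
  bird; serial autocorrelation within trips will make its intervals
  anti-conservative on real 1-min data.
* The UD has no bandwidth selection (fixed *h* by design) and no
  autocorrelation-aware estimator.
* The solar ephemeris is desk-accurate (< 0.2°), not astronomical-grade;
  at ±0.2° the twilight boundary moves by about a minute at 52° N.
* The flock z statistic assumes the rank-sum model; count-model
  alternatives (e.g. a GLM on sizes) would weight large flocks
  differently.
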