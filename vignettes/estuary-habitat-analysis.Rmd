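---
title: "Methods: estuarine habitat-use analysis for satellite-tagged belugas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estuarine habitat-use analysis for satellite-tagged belugas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estuaryuse)
```

## The analysis

Belugas (*Delphinapterus leucas*) aggregate each summer in sub-Arctic
estuaries and leave for their migration in late summer. This package
implements, end to end, an analysis of how such estuary use responds to
river discharge: Argos satellite-telemetry quality control, an estimator of
the residency-to-migration transition date, wet/dry classification of
hydrological years, kernel utilization distributions of the residency
phase, AR1-aware regressions of log distance covariates, and density
indices from strip-transect aerial surveys. Because the original telemetry
and survey records are not publicly deposited, the package also contains a
first-class synthetic-data module that generates tracks, tides, discharge
and surveys with the statistical structure the analysis assumes; every
stage is validated against those generators and against independent oracles
in the test suite.

## Track quality control

Argos delivers several candidate solutions per transmission and a location
class per fix (3, 2, 1, 0, A, B, Z; classes 3-1 carry bounded errors of
roughly 0.25-1.5 km). The QC chain is:

1. **Duplicate resolution** (`dedupe_best()`): within a duplicate group
   (explicit key, or identical whale + timestamp), keep the highest class;
   break ties by receipt order.
2. **Class screen** (`filter_quality()`): retain classes 3, 2, 1 by
   default. Class Z and missing classes always fail.
3. **Travel-rate screen** (`filter_speed()`): a forward single pass per
   whale. The first fix is retained; each subsequent fix is dropped when
   the great-circle speed from the last *retained* fix is at or above
   `vmax` (default 3.5 km/h, a sustained-swim ceiling for belugas). This
   deterministic O(n) filter was chosen over root-mean-style filters
   because it is order-safe, idempotent, and exactly reproducible; the
   test suite proves it equivalent to a brute-force re-implementation on
   short tracks.

Speeds use WGS84 geodesic distances (geosphere) rather than projected
distances because tracks span more than 100 km of coast. Whether the
travel-rate screen should run before or after duplicate resolution is not
determined by the source description; dedupe-first is used, since the
duplicate solutions are alternative estimates of one transmission, not
movement.

## Distance covariates and daily medians

Duty-cycled tags yield unequal fix counts per day, so each whale-day is
collapsed to the componentwise median of longitude and latitude
(`daily_summaries()`). Distance to the river mouth (Port Nelson,
57.0552°N 92.5967°W) and to the nearest shoreline are evaluated *at the
median location*; evaluating the median of per-fix distances is equally
defensible given the ambiguity of "median daily distance", and the daily
summary table retains everything needed to compute it. Shoreline distance
densifies the polyline to 100 m vertex spacing and minimises the geodesic
point-to-vertex distance (worst-case discretisation error about 50 m,
negligible against kilometre-scale covariates). The cross-whale pooled
series (`pooled_daily_distance()`) defaults to the median, with the mean
available, because the source wording supports either.

All planar work (KDE, hulls, the survey frame) uses a local azimuthal
equidistant projection centred on the river mouth (`project_local()`):
distances and bearings from the centre are exact, and distortion over the
~100 km analysis window is small.

## Migration-onset change point

The transition from estuarine residency to migration is estimated with a
distribution-free cumulative sign test (`cumulative_sign_changepoint()`):
each day scores −1 if the pooled daily distance is below the overall
median of the series, +1 if above, 0 on exact ties (a symmetric tie rule;
the source defines only the strict cases); scores are cumulated in day
order and the change point is the day at which |cumulative sum| is
maximal, earliest day on ties. Missing days are skipped, not interpolated.
For a series that switches once from "below median" to "above median",
this estimator locates the crossing day exactly; its sampling error under
Argos noise is quantified by `recover_switch()`, which re-runs the whole
pipeline (simulate → QC → daily medians → pooling → change point) per
replicate and reports bias and MAE against the configured switch day.

## Hydrology

Years are classified on the seasonal (14 July-31 August, 49 days
inclusive) mean of daily discharge. The baseline is the mean of yearly
seasonal means, matching by-year averaging; percent deviation is
`100 (m_y − m_base)/m_base` and a year is *wet* iff its deviation is
strictly positive — average years are dry. The threshold is exposed
(`wet_threshold`) for sensitivity analysis. Windows with more than 10%
of days missing are rejected; smaller gaps warn.

## Kernel utilization distributions

The residency-phase space use is summarised by a fixed bivariate normal
kernel density on a 1 × 1 km grid (`kde_ud()`), normalised to unit mass,
with the isotropic bandwidth chosen by least-squares cross-validation
(`lscv_bandwidth()`): the LSCV criterion is evaluated in closed form from
pairwise squared distances and minimised over `[0.05, 2]` times the
bivariate normal reference bandwidth `σ n^{-1/6}`. A single isotropic h is
used because the source names no per-axis smoothing; duplicate-heavy data
that drive h to the lower bound are clamped there with a warning. The p%
probability contour (`probability_contour()`) is the smallest set of cells,
by descending density, whose mass reaches p/100 — so its attained mass
overshoots by at most one cell's mass, and contours are nested by
construction. Central tendency is reported two ways (`central_points()`):
the geometric mean of locations (computed on positive coordinates after a
false-origin shift) and the density-weighted centre of mass of the 95%
contour cells.

The pre-change-point occupancy polygon (`estuary_polygon()`) is a concave
alpha-shape hull (pair-circle algorithm, written in-package because no
alpha-shape library is available in the dependency set) with a convex-hull
fallback when the boundary does not close into a single ring; `alpha_km`
defaults to 15 km, large enough to close smoothly over daily-median
spacing yet small enough to exclude the land side of a funnel-shaped
fixture. The alpha radius of the original analysis is unrecoverable, so
the polygon's absolute area is not a target — only its mechanism is
validated (square recovery, convex limit, offshore extent).

## AR1 regression and model ranking

Log distance responses are fitted by maximum/restricted maximum likelihood
generalised least squares (nlme::gls) with whale identity as a fixed
blocking factor and an AR1 correlation structure on the within-whale
time-ordered residuals (`fit_model()`). Describing the individual term
simultaneously as a random effect and fitting with gls is internally
contradictory; blocking + AR1 reproduces the correlation structure
actually named, and is the package's documented choice. REML is the
default (less biased covariance parameters); ML is used whenever models
with different fixed effects are compared. Collinearity screening
(`screen_collinearity()`) flags |Pearson r| ≥ 0.6 and VIF > 3.0, with VIF
computed as 1/(1−R²) from regressing each covariate on the rest.

Model ranking uses AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1) with n = the number
of whale-day rows (always echoed in output, since reported model tables
rarely state it), Δ relative to the minimum, and Akaike weights
exp(−Δ/2)/Σexp(−Δ/2). The Durbin-Watson statistic `Σ(e_t−e_{t−1})²/Σe_t²`
is provided separately from likelihood-ratio comparison of correlation
structures; the two are distinct procedures and both are available.
Distribution summaries (`group_summary()`) report median and quartiles
with linear interpolation between order statistics (R type 7), a
documented choice since the original percentile rule is unknown.

## Aerial surveys

The design (`survey_design()`) is ten transects perpendicular to shore,
3.7 km apart, strips of 350 m per side, counting in 15-second intervals
covering ~1 km of track: direct coverage is `2×0.35/3.7 ≈ 19%`
(`coverage_fraction()`). Intervals become 1.0 × 0.7 km (0.7 km²) blocks
with both sides pooled (`bin_to_blocks()`); a stated block area of
"700 m²" in the source is treated as a typographical slip for 0.7 km²,
since 1 km × 0.7 km = 0.7 km². Density-weighted distances use block counts
as weights with a count-weighted variance for the SE; the abundance index
is total count over coverage, explicitly uncorrected for perception or
availability bias. Counts are compared across covariate subsets with
log-link Poisson GLMs (offset log area) ranked by QAICc, using the
overdispersion ĉ from the richest model — "semi Poisson" plus AICc is not
a standard pairing, and QAICc is the documented interpretation. The
survey-replicate tallies follow the survey table (7 in 2003, 10 in 2005)
where the prose swaps them.

## The synthetic generators

The generators define the study conditions the tests exercise:

* **Tracks** (`simulate_tracks()`): 13 whales, 5 July-15 September, switch
  day 221 (9 August). Residency is a discrete-time mean-reverting
  (OU-like) walk with stationary SD 8 km per axis and 1-day correlation
  time, plus a cross-shore offset of 1 km per metre of tide height;
  migration drifts at 30 km/day on bearing 035°. Argos classes are drawn
  with probabilities (3: 0.08, 2: 0.12, 1: 0.15, 0: 0.20, A: 0.25,
  B: 0.20) and isotropic error SDs (0.25, 0.5, 1.5, 5, 10, 20 km); fixes
  per day are Poisson(8), creating the missing days the daily-median stage
  must tolerate; 5% of fixes are duplicated to exercise dedupe. No
  quantitative movement model exists for within-estuary behaviour, so the
  residency parameters are realistic conveniences, not estimates: the
  OU spread and speeds are set so that residency noise (km/h scale) sits
  mostly under the 3.5 km/h screen while migration (1.25 km/h sustained)
  passes it.
* **Discharge** (`simulate_discharge()`): constant year level plus i.i.d.
  daily noise (SD 150 m³/s), so the seasonal-window mean recovers the
  requested year mean and a zero-noise series is exactly constant. The
  default study-year means (3131, 2165, 2831, 5163 m³/s against a 3331
  baseline) reproduce the −6/−35/−15/+55% deviation pattern.
* **Tides** (`simulate_tides()`): a 12.42-h semidiurnal carrier with
  14.77-day envelope modulation (depth 0.45); highs are strict local
  maxima, flagged spring/neap by the median high height.
* **Shoreline** (`make_shoreline()`): a V-shaped funnel opening seaward,
  mouth at the apex, 60 km offshore extent by default.
* **Surveys** (`simulate_survey()`): whale positions drawn uniformly or
  from a supplied density surface over the survey frame; each whale is
  recorded once in the strip interval containing it.

What the generators deliberately do **not** emulate: plume hydrodynamics,
depth or bathymetry, behavioural responses to vessels or predators,
Argos error ellipses (errors are isotropic), and tag failure beyond the
Poisson duty cycle. Passing tests therefore demonstrate that the
*machinery* is correct and that the estimators recover known truth under
plausible noise — not that any particular ecological effect size in real
data is confirmed.

## Numerical choices and problem sizes

* Change-point ties break to the earliest day; all-zero traces are flagged
  degenerate and report the first day.
* KDE grids extend 3.5 h beyond the data and refuse silently truncated
  mass above 1e-3; mass is conserved to 1e-6 after normalisation.
* LSCV uses golden-section search to 1e-4 relative tolerance with the
  closed-form criterion (validated against an O(n²) double loop).
* The validation experiments run at 100 replicates: change-point recovery
  on the full 13-whale pipeline (MAE ≤ 3 days required; the default
  configuration recovers day 221 exactly in every replicate), and AR1
  recovery on 5 × 200 whale-days at φ = 0.6 (all parameter biases within
  2 Monte-Carlo SE). These sizes give the Monte-Carlo precision the
  acceptance bounds need while keeping a full validation run around a
  minute on one core.

## Known limitations

* The alpha-shape ring construction requires every boundary vertex to have
  degree 2; very sparse or multi-cluster data fall back to the convex hull
  (with a warning) rather than returning a multi-part hull.
* `fit_model()` treats whale identity as a fixed blocking factor; variance
  partitioning of a true random effect is out of scope.
* The quasi-Poisson ranking's QAICc shares ĉ across the candidate set (the
  richest model's estimate); comparing ĉ across sets is not meaningful.
* Published coefficient tables from the original field data are not
  reproducible without the raw telemetry, which was never deposited; the
  package validates mechanism, not those estimates.
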