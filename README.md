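# estuaryuse

Tools for analysing summer estuary use by satellite-tagged beluga whales
(*Delphinapterus leucas*) and strip-transect aerial surveys in a
hydroelectrically regulated sub-Arctic estuary — the kind of study that asks
whether whales redistribute between high-discharge ("wet") and
low-discharge ("dry") years, and when the switch from estuarine residency
to autumn migration happens.

The package is aimed at movement ecologists and biotelemetry analysts. It
provides the full pipeline as composable, pipe-friendly functions over data
frames:

* **Argos quality control** — duplicate resolution (best location class
  wins), a class screen (retain "guaranteed" classes 3/2/1), and a forward
  travel-rate filter dropping fixes that imply ≥ 3.5 km/h from the last
  retained fix.
* **Distance covariates** — daily componentwise-median locations per whale,
  geodesic distance to the river mouth (Port Nelson, 57.0552°N 92.5967°W)
  and to the nearest shoreline, pooled across whales by day of year.
* **Migration-onset change point** — the distribution-free cumulative sign
  test: day *t* scores sᵗ = sign(dᵗ − median(d)); the change point is
  argmaxₜ |Σᵤ≤ₜ sᵘ|.
* **Hydrological-year classification** — seasonal (14 Jul–31 Aug) mean
  discharge per year, percent deviation 100(mᵧ − m̄)/m̄ from a multi-year
  baseline, wet iff deviation > 0.
* **Kernel utilization distributions** — fixed bivariate normal kernel on a
  1-km grid with least-squares cross-validated bandwidth, p% probability
  contours (smallest cell set holding p% of mass), geometric-mean and
  centre-of-mass summaries, and a concave (alpha-shape) estuary polygon.
* **AR1-aware inference** — GLS fits of log-distance responses with
  within-whale AR1 residuals, collinearity screening (|r| ≥ 0.6,
  VIF > 3), AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), Δ-based Akaike weights,
  Durbin–Watson statistics, and quartile summaries.
* **Survey analysis** — strip-transect design math (coverage =
  2·half-width/spacing), 1.0 × 0.7 km block binning, density-weighted
  distances, an uncorrected abundance index, and QAICc-ranked
  quasi-Poisson density models.
* **Synthetic data** — generators for two-phase whale tracks (OU residency
  + directed migration, tide coupling, Argos class errors, duty cycling),
  discharge series, spring/neap tides, a funnel shoreline, and aerial
  surveys, so the whole pipeline runs and is tested without field data.

## Worked example

```r
library(estuaryuse)

cfg   <- sim_config(seed = 1)          # 13 whales, switch day 221 (9 Aug)
fixes <- simulate_tracks(cfg)
qc    <- qc_tracks(fixes)
qc$report
#>   n_input n_after_dedupe n_after_quality n_after_speed retention_fraction
#> 1    8076           7664            2769          2390          0.2959386

daily  <- daily_summaries(qc$fixes)
pooled <- pooled_daily_distance(daily)
cp     <- cumulative_sign_changepoint(pooled[, c("day_of_year", "distance")])
cp
#> Cumulative-sign change point
#>   change day of year: 221 (|cumsum| max = 36 over 73 days)
```

The QC chain kept 29.6% of the simulated Argos fixes (most losses are the
low-quality classes 0/A/B), and the cumulative sign test put the
residency-to-migration change point on day of year 221 — exactly the switch
day the simulation was configured with.

```r
classify_wet_dry(
  c(`2002` = 3131, `2003` = 2165, `2004` = 2831, `2005` = 5163),
  baseline_mean = 3331)
#>    year seasonal_mean baseline_mean deviation_pct deviation_pct_int label
#> 1  2002          3131          3331         -6.00                -6   dry
#> 2  2003          2165          3331        -35.00               -35   dry
#> 3  2004          2831          3331        -15.01               -15   dry
#> 4  2005          5163          3331         55.00                55   wet

coverage_fraction(survey_design())   # 350 m strips, 3.7 km spacing
#> [1] 0.1891892                      # ~19% direct coverage
```

Plots: `autoplot(cp)` draws the |cumulative sum| trace with the estimated
change day; `autoplot(kde_ud(...))` maps a utilization distribution with
contour overlays; `tidy()`/`glance()` methods give broom-style access to
every fitted object.

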