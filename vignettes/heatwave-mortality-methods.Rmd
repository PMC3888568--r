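---
title: "Methods: projecting heat-wave-attributable excess mortality with uncertainty decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting heat-wave-attributable excess mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmort)
```

`heatmort` implements a county-level projection of excess mortality
attributable to future heat waves, together with a first-order variance
decomposition of the projection's uncertainty. This vignette describes the
statistical procedure, the assumptions behind each stage, the parameters
that matter and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
methodology was genuinely open.

## The pipeline at a glance

1. **Synthetic inputs** (`generate_counties()`, `generate_temperatures()`,
   `generate_stations()`): seeded counties with demography, daily
   warm-season temperature series for a baseline and one or more warmer
   future periods, and station observations related to the modeled series
   by a known multiplicative bias.
2. **Calibration** (`compute_county_ratios()`,
   `interpolate_fixed_radius()`, `interpolate_nearest_k()`,
   `apply_calibration()`): model-to-observation ratios at station
   counties, spatially interpolated to all counties by either a fixed
   150-km search radius or the five nearest ratios, then applied by
   division.
3. **Heat-wave detection** (`compute_thresholds()`, `detect_heatwaves()`):
   four operational definitions based on the heat index, daily mean, daily
   maximum (Meehl–Tebaldi), and daily minimum temperature, with baseline
   percentile thresholds and absolute floors.
4. **Mortality** (`sample_ar_sets()`, `project_population()`,
   `estimate_scenario()`): excess deaths per event from
   `ED = N × (RR − 1) × L`, with region-specific attributable risks
   sampled by Latin hypercube and populations projected by the
   constant-ratio method under four migration assumptions.
5. **Uncertainty** (`build_grid()`, `summarize_distribution()`,
   `variance_decomposition()`): a complete balanced factor grid of total
   annual excess deaths — emissions scenario × calibration method ×
   definition × population scenario × AR set × year — summarized as a
   distribution and decomposed into first-order sensitivity indices.

`run_pipeline()` executes all stages from one configuration list under a
single master seed; per-stage seeds are derived by a fixed counter scheme
(`derive_seed()`) so any stage can be rerun in isolation.

## Synthetic climate model

Daily mean temperature for county *c* on season day *t* is

> T(c, t) = m(c) − A·cos(2πs) + w + e(t),  s = (t − ½)/n

with `m(c)` the county mean (a domain mean plus a latitudinal gradient),
`A` the seasonal half-amplitude over the 1 May – 30 Sep window, `w` the
scenario warming offset, and `e(t)` a stationary AR(1) process. Hot spells
are additive bumps over consecutive days, with per-season counts drawn
from a Poisson distribution and lengths uniform on {2,…,7} — a range that
spans the minimum-length criteria of all four definitions so recovery can
be tested per definition. Every injected spell is recorded in a truth log.
Daily maximum and minimum are fixed offsets (+6.0 / −5.4 °C) from the
daily mean; dew point is the daily mean minus a nonnegative spread so
heat-index inputs always exist.

Defaults are chosen once to represent eastern-US warm-season conditions at
the county scale and are not revisited:

| parameter | default | rationale |
|---|---|---|
| `mean_tavg` | 22.7 °C | domain-mean May–Sep daily average for the eastern US |
| `seasonal_amplitude` | 4.5 °C | span of May–Sep monthly means (May ≈ 18, Jul ≈ 27 °C) |
| `tmax_offset`, `tmin_offset` | 6.0, 5.4 °C | mean summer offsets of T_max and T_min from T_avg; the same offsets generate the 32.7 / 21.3 °C threshold floors from the 26.7 °C mean floor |
| `lat_gradient` | 1.0 °C/deg | summer mean temperature change per degree latitude |
| `dewpoint_spread` | 6 °C | typical daily-mean dew-point depression in humid summers |
| `noise_sd`, `noise_autocorr` | 3 °C, 0.4 | day-to-day variability of daily means; moderate persistence |
| `warming_offset` | 2.0 / 3.0 °C | moderate- vs high-emission mid-century warming, ~1 °C scenario separation |
| `hotspell_rate`, `hotspell_bump` | 1.5/season, +4 °C | a few multi-day anomalies per season on top of the smooth cycle |
| `station_bias`, `station_fraction` | 1.05, 0.4 | a few percent of model warm bias; roughly the observed fraction of counties hosting stations |

Counties sit on a jittered grid at fixed density (≈0.5° between
centroids, the eastern-US county spacing), so the domain grows with the
county count up to a rectangle spanning ~10° latitude. Density rather
than extent is held fixed because the 150-km search radius is only
meaningful — and only guaranteed non-empty — at realistic station-network
density; at desk scale a fixed 10° rectangle would leave most counties
with an empty radius, which the radius was chosen to preclude.

**What the generator does not emulate.** Real gridded model output
aggregated from ~250,000 grid cells (series are generated per county
directly); real geography, coastlines, or urban heat islands; the full
~20° latitudinal temperature spread of the eastern US (the compressed
domain means the absolute threshold floors bind less often than they do
in reality, so synthetic baseline heat-wave frequencies run higher than
published eastern-US values); humidity that varies independently of
temperature; and population age structure. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
structure, not climatological fidelity of any particular county.

## Calibration

At each station county the ratio is (period mean of model) / (period mean
of observations), per variable, after two preparatory steps: multiple
stations in a county are averaged per day, and county-days whose observed
value exceeds the 99th percentile of that county's observations are
excluded (screening the hottest-tail days, where model–station
disagreement is largest). Calibration is applied by division, which maps
the model onto the observation scale and is order-preserving within each
county-variable. Two points were genuinely open and are set by argument:

* whether the exclusion quantile is per county or pooled across all
  stations (`quantile_scope`, default per county, matching the ratio's
  county-level unit);
* ratios are computed per variable (T_avg, T_max, T_min) rather than once
  per county; dew point is divided by the T_avg ratio so the humidity
  input stays consistent with the calibrated mean.

Future-period series are calibrated with baseline-derived ratios — bias
is assumed stationary, as no future recalibration is available.
Distances are great-circle on a 6371-km sphere (haversine via
`geosphere`); county-scale distances do not warrant an ellipsoid. In
`interpolate_nearest_k()` distances are rounded to the millimetre before
ordering so exact geometric ties resolve by ascending county id rather
than floating-point noise.

## Heat-wave definitions

All percentile thresholds are computed per county from all baseline
season days pooled across years, using linear interpolation between order
statistics (quantile type 7) — the most common convention, fixed
package-wide for reproducibility. Floors are applied as
`max(percentile, floor)`.

Comparison conventions follow the definitions as printed: strict `>` for
percentile thresholds, `≥` ("no less than") for the two NWS heat-index
thresholds. Events are confined to the May–September season and never
span years. Three ambiguities were resolved as follows (alternatives
remain available in `hwd_config()`):

* **Heat-index events may have length 1.** The definition qualifies
  individual days, not runs; `min_len_hi` can impose ≥2 if the stricter
  original reading is wanted.
* **The 32.7 °C floor applies to the Meehl–Tebaldi upper threshold T1
  only** (`tmax_floor_applies = "both"` floors T2 as well, capped at T1).
* **Daily heat-index extremes** are computed from daily T_min and T_max
  with the single daily dew point (the package's inputs are daily, not
  hourly); dew point is capped at the air temperature, i.e. saturation at
  the nighttime minimum.

The Meehl–Tebaldi search reports, within each maximal run of days above
T2, the longest window containing at least three days above T1 with
window mean above T1; the earliest window wins among equal lengths. The
implementation scans runs with cumulative sums and is verified in the
tests against exhaustive enumeration of every window — all 3-level series
up to length 8 (9,840 series) plus seeded random series up to length 20.

## Mortality model

Excess deaths for one event are `ED = N × (RR − 1) × L`: `N` the expected
daily non-heat-wave deaths (baseline non-accidental daily mortality rate ×
population — heat-wave days are not excluded from the person-time
denominator, following the printed form), `RR − 1` the attributable risk,
`L` the event length. Negative contributions from the South range's
protective lower bound are retained, not clamped. All counties in a
region share one AR value within a sampled set; AR values estimated under
the daily-mean definition are applied to all four definitions — a known
caveat inherited from the source methodology. The default regional AR
ranges are the published intervals: Northeast 1.79–11.98 %, Midwest
3.36–7.93 %, South −0.11–3.84 %.

Latin hypercube sampling (via the `lhs` package) draws 100 joint AR sets
with exactly one draw in each of the 100 equal-probability strata per
region; nine sets are then selected uniformly without replacement.

Populations use the constant-ratio method: county share of the state's
2000 population × the state's 2050 projection, held constant over the
projection years (projections end at 2050; no extrapolation is invented).
The four migration scenarios (high, constant/medium, low, zero) default
to multipliers 1.60 / 1.45 / 1.35 / 1.15 of the 2000 state populations,
in the decreasing order of published cohort-component projections.

## Uncertainty analysis

The factor grid is a complete balanced design — 2 scenarios × 2
calibration methods × 4 definitions × 4 population scenarios × 9 AR sets
× 3 years = 1,728 cells under the defaults. The decomposition is the
first-order Sobol/ANOVA form for independent discrete factors:
`S_i = V(E[y | x_i]) / V(y)`, with population (denominator *n*) variance
throughout so main effects add exactly on balanced grids; all
higher-order terms are pooled into a single interactions share
`1 − Σ S_i`. Confidence intervals are empirical percentiles of the pooled
grid (not normal-theory), matching the distributional presentation of the
estimates. A constant response yields all-zero indices with a warning
rather than 0/0.

```{r decomposition-example}
g <- expand.grid(x1 = c("0", "1"), x2 = c("0", "3"),
                 stringsAsFactors = FALSE)
g$total_excess_deaths <- as.numeric(g$x1) + as.numeric(g$x2)
variance_decomposition(g, factors = c("x1", "x2"))
```

## A small end-to-end run

```{r pipeline, eval = TRUE}
cfg <- default_config(n_counties = 12, n_states = 3,
                      baseline_years = 2001:2002,
                      future_years = 2058:2059, seed = 42)
res <- run_pipeline(cfg)
res$sensitivity
round(res$distribution$overall$mean, 1)
```

Under the default synthetic conditions the attributable-risk sets, the
emissions scenario, and the heat-wave definition carry the large
sensitivity indices, while calibration method, population scenario, and
projection year are minor — the qualitative ranking the method is
designed to expose. The acceptance tests assert that ranking on the mean
indices over five seeds at 30 counties.

## Problem sizes and runtimes

The package's own analyses are run at desk scale by choice: 12–60
counties, 2–4 baseline and 2–3 future years. The test suite builds all
fixtures in code (no stored data); the exhaustive Meehl–Tebaldi sweep and
the 50-county interpolation oracles complete in well under a minute, and
a 30-county end-to-end pipeline takes a few seconds. Frequencies and
sensitivity indices at this scale have visible seed-to-seed variability —
hence ranking, not value, assertions for the stochastic properties.

## Known limitations

* The binary heat-wave/no-heat-wave risk model ignores intensity: future
  events are hotter, not just longer and more frequent, so the estimates
  are conservative in that respect.
* No adaptation, acclimatization, urban/rural effect modification, or
  demographic-structure change.
* Synthetic baseline heat-wave frequencies exceed published eastern-US
  values because the compressed spatial domain mutes the absolute floors
  (see above); cross-scenario *ratios* and variance shares, not absolute
  event counts, are the quantities the synthetic conditions are designed
  to reproduce.
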