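# heatmort

County-level projection of excess mortality attributable to future heat
waves, with a variance decomposition of where the uncertainty comes from.
The package is aimed at environmental-health and climate-impact analysts
who need the full chain — temperature bias calibration, heat-wave
detection under competing definitions, attributable-risk mortality, and
scenario uncertainty — as tested, seeded, reusable code. A synthetic-data
module generates counties, daily temperature fields, station
observations, and demography with the statistical structure the analysis
assumes, so every stage runs and is testable with no external climate,
station, or census data.

## The method

**Calibration.** Modeled county temperature series are calibrated against
station observations by the ratio method: at each station county,
ratio = mean(model) / mean(obs) per variable, after per-day averaging of
multiple stations and exclusion of observed days above the county's 99th
percentile. Ratios are interpolated to all counties either as the mean of
all ratios within a fixed 150-km great-circle radius of the county
centroid, or as the mean of the 5 nearest ratios, and applied by
division.

**Heat-wave definitions.** Four operational definitions are detected per
county and season (1 May – 30 Sep):

| definition | criterion |
|---|---|
| HWD_HI | days whose daily low and high NWS heat index are ≥ 26.7 °C (80 °F) and ≥ 40.5 °C (105 °F) |
| HWD_Tavg | ≥ 2 consecutive days with T_avg > the baseline 95th percentile |
| HWD_Tmax | Meehl–Tebaldi: longest window with ≥ 3 days of T_max > the 97.5th percentile (T1), window mean > T1, every day > the 81.5th percentile (T2) |
| HWD_Tmin | ≥ 2 consecutive days with T_min > the baseline 95th percentile |

Percentile thresholds are floored at 26.7 °C (T_avg), 21.3 °C (T_min),
and 32.7 °C (T_max), the latter two derived from the first via the mean
summer offsets T_avg − T_min = 5.4 °C and T_max − T_avg = 6 °C.

**Mortality.** Each event of length *L* days in a county with expected
daily non-heat-wave deaths *N* contributes

    ED_hw = N × (RR − 1) × L

excess deaths, where RR − 1 is the attributable risk (AR). ARs are
region-specific (Northeast 1.79–11.98 %, Midwest 3.36–7.93 %, South
−0.11–3.84 %), sampled by Latin hypercube (100 stratified draws, 9 sets
selected). Populations follow the constant-ratio method under four
migration scenarios.

**Uncertainty.** Total annual excess deaths are evaluated on the complete
balanced grid of emissions scenario × calibration method × definition ×
population scenario × AR set × year (2·2·4·4·9·3 = 1,728 cells) and
decomposed into first-order sensitivity indices
S_i = V(E[y | x_i]) / V(y), with interactions pooled into the residual
1 − Σ S_i.

## Worked example

```r
library(heatmort)

cfg <- default_config(n_counties = 20, n_states = 4, seed = 7)
res <- run_pipeline(cfg)

subset(res$frequency$future, definition != "all")
#>  definition frequency duration_mean
#>      HWD_HI      6.15          1.55
#>    HWD_Tavg      5.20          3.25
#>    HWD_Tmax      1.61          9.38
#>    HWD_Tmin      5.20          3.25

res$distribution$overall$mean          # 49.9 deaths/year
c(res$distribution$rcp45$mean,         # 34.5 under the moderate scenario
  res$distribution$rcp85$mean)         # 65.4 under the high-emission scenario
res$baseline$distribution$mean         # 6.8 in the baseline period

res$sensitivity
#>        factor   S_i
#>           rcp 0.271
#>   calibration 0.000
#>           hwd 0.142
#>  pop_scenario 0.039
#>        ar_set 0.398
#>          year 0.001
#>  interactions 0.148
```

The frequency table gives episodes/year/county and mean duration in days
per definition, integrated over both scenarios and calibration methods.
The distribution means are total annual excess deaths over the 20
synthetic counties, pooled over the 1,152-cell factor grid (here 2 fewer
year levels than the default). The sensitivity table shows the share of
variance in those totals explained by each factor's main effect: the
attributable-risk sets, the emissions scenario, and the heat-wave
definition dominate, while the calibration method, population scenario,
and model year are minor — the same qualitative ranking reported for the
real eastern-US domain.

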