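#' Literature benchmark summary for the eastern US projection
#'
#' Published benchmark estimates of warm-season mean temperature, heat-wave
#' frequency, duration, and total heat-wave-attributable excess deaths for
#' the ~1,700-county eastern United States domain: the 2002-2004 baseline
#' and the 2057-2059 projection (combined and per emissions scenario).
#' These values are literature inputs, like the regional attributable-risk
#' ranges; the package uses them only for arithmetic consistency checks
#' (e.g. future/baseline mortality and frequency ratios), never as a
#' substitute for its own computations.
#'
#' @return data frame with `period`, `tavg_c`, `frequency`
#'   (episodes/year/county), `duration_days`, `excess_deaths` (deaths/year).
#' @export
reference_summary <- function() {
  data.frame(
    period = c("baseline", "future_combined", "future_rcp45", "future_rcp85"),
    tavg_c = c(22.74, 24.75, 24.11, 25.39),
    frequency = c(0.38, 1.88, 1.31, 2.44),
    duration_days = c(3.44, 4.53, 4.06, 4.85),
    excess_deaths = c(187, 2379, 1403, 3556),
    stringsAsFactors = FALSE)
}

#' Benchmark mortality and frequency ratios
#'
#' Future-to-baseline ratios implied by the benchmark summary: the
#' mortality ratio under each emissions scenario (the "7.5 to 19.0 times
#' higher" span) and the heat-wave frequency ratio.
#'
#' @return named numeric vector with `mortality_ratio_rcp45`,
#'   `mortality_ratio_rcp85`, `frequency_ratio_rcp85`,
#'   `frequency_ratio_rcp45`.
#' @export
reference_ratios <- function() {
  rs <- reference_summary()
  v <- function(p, col) rs[[col]][rs$period == p]
  c(mortality_ratio_rcp45 = v("future_rcp45", "excess_deaths") / v("baseline", "excess_deaths"),
    mortality_ratio_rcp85 = v("future_rcp85", "excess_deaths") / v("baseline", "excess_deaths"),
    frequency_ratio_rcp45 = v("future_rcp45", "frequency") / v("baseline", "frequency"),
    frequency_ratio_rcp85 = v("future_rcp85", "frequency") / v("baseline", "frequency"))
}
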