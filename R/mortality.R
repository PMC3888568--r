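#' Default regional attributable-risk ranges
#'
#' Published 95% confidence intervals for the percentage increase in
#' non-accidental mortality on heat-wave days relative to non-heat-wave
#' days, by region, used as uniform sampling ranges for the attributable
#' risk AR = RR - 1: Northeast 1.79-11.98%, Midwest 3.36-7.93%, South
#' -0.11 to 3.84% (the South range admits slightly protective values,
#' which are retained, not clamped).
#'
#' @return data frame with `region`, `ar_low`, `ar_high` (fractions).
#' @export
default_ar_ranges <- function() {
  data.frame(region = hw_regions(),
             ar_low = c(0.0179, 0.0336, -0.0011),
             ar_high = c(0.1198, 0.0793, 0.0384),
             stringsAsFactors = FALSE)
}

#' Sample regional attributable-risk sets by Latin hypercube
#'
#' Draws `n_samples` joint AR sets (one value per region) from independent
#' uniform distributions over the regional ranges using Latin hypercube
#' sampling, so each region's `n_samples` equal-probability strata each
#' contain exactly one draw; then selects `n_select` of the joint sets
#' uniformly without replacement. Deterministic given the seed.
#'
#' @param ranges data frame as returned by [default_ar_ranges()].
#' @param n_samples number of LHS draws (default 100).
#' @param n_select number of joint sets selected (default 9).
#' @param seed integer RNG seed.
#' @return data frame with `set_index` and one AR column per region; the
#'   full `n_samples` x regions draw matrix is attached as attribute
#'   `"samples"`.
#' @export
sample_ar_sets <- function(ranges = default_ar_ranges(), n_samples = 100L,
                           n_select = 9L, seed = 1L) {
  if (any(!is.finite(ranges$ar_low)) || any(!is.finite(ranges$ar_high)))
    stop("AR ranges must be finite")
  if (any(ranges$ar_low > ranges$ar_high))
    stop("AR range lower bounds must not exceed upper bounds")
  if (n_select > n_samples) stop("n_select must not exceed n_samples")
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n_samples, nrow(ranges))
  samples <- sweep(u, 2, ranges$ar_high - ranges$ar_low, `*`)
  samples <- sweep(samples, 2, ranges$ar_low, `+`)
  colnames(samples) <- ranges$region
  sel <- sort(sample.int(n_samples, n_select))
  out <- data.frame(set_index = seq_len(n_select), samples[sel, , drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' Project county populations by the constant-ratio method
#'
#' County population = census-projected state population in 2050 under the
#' chosen migration scenario, multiplied by the county's baseline (2000)
#' share of its state's population; each county's share is assumed constant
#' over time, and the 2050 projection is held constant over the projection
#' years.
#'
#' @param demography county data frame with `state_id` and `state_share`.
#' @param state_projections data frame with `state_id`, `scenario`,
#'   `pop_2050`.
#' @param scenario migration scenario label to project under.
#' @return data frame with `county_id` and `pop` (persons).
#' @export
project_population <- function(demography, state_projections, scenario) {
  proj <- state_projections[state_projections$scenario == scenario, ]
  idx <- match(demography$state_id, proj$state_id)
  if (anyNA(idx)) {
    missing <- unique(demography$state_id[is.na(idx)])
    stop("no ", scenario, " projection for states: ",
         paste(missing, collapse = ", "))
  }
  data.frame(county_id = demography$county_id,
             pop = proj$pop_2050[idx] * demography$state_share,
             stringsAsFactors = FALSE)
}

#' Excess deaths attributable to one heat wave
#'
#' `ED = N x (RR - 1) x L`, where `N` is the expected number of deaths per
#' day on non-heat-wave days (daily mortality rate times population), `RR`
#' the relative risk of death on heat-wave days, and `L` the event length
#' in days. Negative values (RR < 1, protective) are propagated.
#'
#' @param n_deaths_day expected non-heat-wave deaths per day (>= 0).
#' @param rr relative risk (may be below 1).
#' @param length_days heat-wave length in days (>= 1).
#' @return excess deaths, vectorized over the inputs.
#' @export
excess_deaths <- function(n_deaths_day, rr, length_days) {
  if (any(n_deaths_day < 0)) stop("N must be >= 0")
  if (any(length_days < 1)) stop("L must be >= 1")
  n_deaths_day * (rr - 1) * length_days
}

#' Excess deaths for one scenario cell
#'
#' Applies the attributable-risk model to a set of detected events: for
#' each event, expected daily deaths `N` are the county's baseline daily
#' mortality rate times its (projected) population, the AR is the value of
#' the county's region in `ar_set`, and the event contributes
#' `N x AR x L` excess deaths. Contributions are summed per county and in
#' total.
#'
#' @param events event data frame (one definition / scenario / year).
#' @param demography county data frame (`county_id`, `region`,
#'   `mortality_rate`).
#' @param ar_set named numeric vector of ARs by region (fractions), or a
#'   one-row slice of [sample_ar_sets()] output.
#' @param population data frame `county_id`, `pop` (e.g. from
#'   [project_population()]), or a single named vector.
#' @return list with `total` (deaths) and `per_county` (data frame
#'   `county_id`, `excess_deaths`).
#' @export
estimate_scenario <- function(events, demography, ar_set, population) {
  if (is.data.frame(ar_set)) {
    regs <- intersect(names(ar_set), hw_regions())
    ar_set <- unlist(ar_set[1, regs])
  }
  if (is.data.frame(population)) {
    pop <- population$pop
    names(pop) <- population$county_id
  } else pop <- population

  per_county <- data.frame(county_id = demography$county_id,
                           excess_deaths = 0, stringsAsFactors = FALSE)
  if (nrow(events) > 0) {
    di <- match(events$county_id, demography$county_id)
    if (anyNA(di))
      stop("events in counties without demography: ",
           paste(unique(events$county_id[is.na(di)]), collapse = ", "))
    if (anyNA(pop[demography$county_id[di]]))
      stop("missing population for some event counties")
    n_day <- demography$mortality_rate[di] * pop[demography$county_id[di]]
    ar <- ar_set[demography$region[di]]
    if (anyNA(ar)) stop("ar_set lacks a value for some region")
    ed <- excess_deaths(n_day, 1 + ar, events$length_days)
    agg <- tapply(ed, events$county_id, sum)
    per_county$excess_deaths <- as.numeric(agg[per_county$county_id])
    per_county$excess_deaths[is.na(per_county$excess_deaths)] <- 0
  }
  list(total = sum(per_county$excess_deaths), per_county = per_county)
}
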