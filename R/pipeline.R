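#' Default end-to-end run configuration
#'
#' One nested list drives the whole pipeline: the synthetic-data block, the
#' scenario warming offsets, calibration settings, heat-wave definition
#' configuration, population-projection multipliers, and attributable-risk
#' sampling. A single master seed derives per-stage seeds by a fixed
#' counter scheme (see [derive_seed()]), so reruns with the same config are
#' identical.
#'
#' @param n_counties,n_states size of the synthetic domain.
#' @param baseline_years,future_years simulated year ranges (baseline
#'   supplies the percentile thresholds and the baseline mortality rows).
#' @param seed master seed.
#' @param climate a [climate_params()] object.
#' @param warming named vector of scenario warming offsets, degrees C.
#' @param calibration list with `methods`, `radius_km`, `k`,
#'   `exclusion_quantile`.
#' @param hwd an [hwd_config()] object.
#' @param pop_multipliers named state-projection growth multipliers.
#' @param ar list with `ranges`, `n_samples`, `n_select`.
#' @param thresholds_deaths thresholds at which cumulative probabilities of
#'   the annual-death distribution are reported.
#' @return a config list.
#' @export
default_config <- function(n_counties = 30L, n_states = 6L,
                           baseline_years = 2001:2004,
                           future_years = 2057:2059,
                           seed = 1L,
                           climate = climate_params(),
                           warming = c(rcp45 = 2.0, rcp85 = 3.0),
                           calibration = list(methods = c("fixed_radius", "nearest_k"),
                                              radius_km = 150, k = 5,
                                              exclusion_quantile = 0.99),
                           hwd = hwd_config(),
                           pop_multipliers = c(high = 1.60, constant_medium = 1.45,
                                               low = 1.35, zero = 1.15),
                           ar = list(ranges = default_ar_ranges(),
                                     n_samples = 100L, n_select = 9L),
                           thresholds_deaths = c(1000, 2000, 5000)) {
  list(n_counties = as.integer(n_counties), n_states = as.integer(n_states),
       baseline_years = as.integer(baseline_years),
       future_years = as.integer(future_years),
       seed = as.integer(seed), climate = climate, warming = warming,
       calibration = calibration, hwd = hwd,
       pop_multipliers = pop_multipliers, ar = ar,
       thresholds_deaths = thresholds_deaths)
}

#' Run the full projection pipeline
#'
#' Executes every stage on seeded synthetic data: county and demography
#' generation; baseline and per-scenario future temperature fields; station
#' observations; calibration ratios interpolated by both rules and applied
#' to all series; baseline percentile thresholds; heat-wave detection under
#' all four definitions for every (scenario, calibration, year); population
#' projections under the four migration scenarios; Latin-hypercube AR sets;
#' the full factor grid of total excess deaths; distribution summaries; and
#' the first-order variance decomposition. Optionally writes all outputs as
#' CSV plus a JSON manifest.
#'
#' @param config configuration list from [default_config()].
#' @param outdir optional output directory; created if needed.
#' @param verbose print stage progress.
#' @return a list with elements `counties`, `stations`, `station_ratios`,
#'   `ratios` (per method), `thresholds` (per method), `events` (baseline
#'   and future, with `period`, `rcp`, `calibration` columns), `spells`
#'   (injection truth logs), `populations`, `ar_sets`, `grid`,
#'   `distribution` (overall and per scenario), `baseline` (baseline-period
#'   mortality distribution and frequency summary), `frequency` (summary
#'   tables), `sensitivity`, and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cl <- config$climate

  say("generating counties")
  counties <- stage("counties",
    generate_counties(config$n_counties, config$n_states,
                      derive_seed(config$seed, 1)))

  say("generating temperatures")
  base <- stage("baseline temperatures", {
    p <- cl; p$seed <- derive_seed(config$seed, 2)
    generate_temperatures(counties, p, config$baseline_years, warming_offset = 0)
  })
  futures <- stage("future temperatures", {
    out <- list()
    for (i in seq_along(config$warming)) {
      p <- cl; p$seed <- derive_seed(config$seed, 2 + i)
      out[[names(config$warming)[i]]] <-
        generate_temperatures(counties, p, config$future_years,
                              warming_offset = config$warming[[i]])
    }
    out
  })

  say("generating stations and calibrating")
  stations <- stage("stations", {
    p <- cl; p$seed <- derive_seed(config$seed, 6)
    generate_stations(base$series, counties, p)
  })
  station_ratios <- stage("station ratios",
    compute_county_ratios(base$series, stations,
                          config$calibration$exclusion_quantile))
  ratios <- list()
  for (m in config$calibration$methods) {
    ratios[[m]] <- stage(paste("interpolation", m),
      if (m == "fixed_radius")
        interpolate_fixed_radius(station_ratios, counties,
                                 config$calibration$radius_km)
      else interpolate_nearest_k(station_ratios, counties,
                                 config$calibration$k))
  }

  say("computing thresholds and detecting heat waves")
  thresholds <- list(); events <- list(); runs <- list()
  for (m in names(ratios)) {
    cal_base <- apply_calibration(base$series, ratios[[m]])
    thresholds[[m]] <- stage(paste("thresholds", m),
      compute_thresholds(cal_base, config$hwd))
    ev_b <- stage(paste("baseline detection", m),
      detect_heatwaves(cal_base, thresholds[[m]], config$hwd))
    if (nrow(ev_b)) { ev_b$rcp <- "baseline"; ev_b$calibration <- m; ev_b$period <- "baseline" }
    events[[paste0("baseline_", m)]] <- ev_b
    for (sc in names(futures)) {
      cal_fut <- apply_calibration(futures[[sc]]$series, ratios[[m]])
      ev <- stage(paste("detection", m, sc),
        detect_heatwaves(cal_fut, thresholds[[m]], config$hwd))
      if (nrow(ev)) { ev$rcp <- sc; ev$calibration <- m; ev$period <- "future" }
      events[[paste0(sc, "_", m)]] <- ev
      for (d in hwd_kinds()) for (yr in config$future_years)
        runs[[length(runs) + 1L]] <- data.frame(
          rcp = sc, calibration = m, definition = d, year = yr,
          stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, c(events[vapply(events, nrow, 0L) > 0],
                             list(cbind(empty_events(),
                                        rcp = character(), calibration = character(),
                                        period = character()))))
  rownames(events) <- NULL
  runs <- do.call(rbind, runs)

  say("projecting populations and sampling AR sets")
  state_proj <- generate_state_projections(counties, config$pop_multipliers)
  populations <- do.call(rbind, lapply(names(config$pop_multipliers), function(sc) {
    p <- project_population(counties, state_proj, sc)
    data.frame(scenario = sc, p, stringsAsFactors = FALSE)
  }))
  ar_sets <- stage("AR sampling",
    sample_ar_sets(config$ar$ranges, config$ar$n_samples, config$ar$n_select,
                   derive_seed(config$seed, 7)))

  say("building the factor grid")
  fut_events <- events[events$period == "future", , drop = FALSE]
  grid <- stage("grid",
    build_grid(fut_events, counties, ar_sets, populations,
               rcps = names(config$warming),
               calibrations = config$calibration$methods,
               years = config$future_years, evaluated = runs))

  say("summarizing and decomposing variance")
  distribution <- list(
    overall = summarize_distribution(grid$total_excess_deaths,
                                     thresholds = config$thresholds_deaths))
  for (sc in names(config$warming))
    distribution[[sc]] <- summarize_distribution(
      grid$total_excess_deaths[grid$rcp == sc],
      thresholds = config$thresholds_deaths)
  sensitivity <- stage("variance decomposition",
    variance_decomposition(grid,
      factors = c("rcp", "calibration", "hwd", "pop_scenario", "ar_set", "year")))

  # baseline-period mortality: baseline events, baseline (2000) populations
  base_events <- events[events$period == "baseline", , drop = FALSE]
  base_pop <- data.frame(county_id = counties$county_id, pop = counties$pop_2000,
                         stringsAsFactors = FALSE)
  base_totals <- c()
  for (m in config$calibration$methods) for (d in hwd_kinds())
    for (yr in config$baseline_years) for (a in seq_len(nrow(ar_sets))) {
      ev <- base_events[base_events$calibration == m &
                          base_events$definition == d &
                          base_events$year == yr, , drop = FALSE]
      base_totals <- c(base_totals,
        estimate_scenario(ev, counties, ar_sets[a, ], base_pop)$total)
    }
  baseline <- list(
    distribution = summarize_distribution(base_totals),
    frequency = summarize_events(base_events,
                                 n_years = length(config$baseline_years) *
                                   length(config$calibration$methods),
                                 n_counties = config$n_counties))

  frequency <- list(
    baseline = baseline$frequency,
    future = summarize_events(fut_events,
                              n_years = length(config$future_years) *
                                length(config$calibration$methods) *
                                length(config$warming),
                              n_counties = config$n_counties))
  for (sc in names(config$warming))
    frequency[[sc]] <- summarize_events(
      fut_events[fut_events$rcp == sc, , drop = FALSE],
      n_years = length(config$future_years) * length(config$calibration$methods),
      n_counties = config$n_counties)

  manifest <- list(seed = config$seed,
                   n_counties = config$n_counties,
                   n_states = config$n_states,
                   baseline_years = config$baseline_years,
                   future_years = config$future_years,
                   rows = list(counties = nrow(counties),
                               stations = nrow(stations),
                               events = nrow(events),
                               grid = nrow(grid)))

  result <- list(counties = counties, stations = stations,
                 station_ratios = station_ratios, ratios = ratios,
                 thresholds = thresholds, events = events,
                 spells = list(baseline = base$spells,
                               future = lapply(futures, `[[`, "spells")),
                 populations = populations, ar_sets = ar_sets, grid = grid,
                 distribution = distribution, baseline = baseline,
                 frequency = frequency, sensitivity = sensitivity,
                 manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) utils::write.csv(x, file.path(outdir, f), row.names = FALSE)
    w(counties, "counties.csv")
    w(stations, "stations.csv")
    w(do.call(rbind, ratios), "ratios.csv")
    w(events, "events.csv")
    w(grid, "grid.csv")
    w(sensitivity, "sensitivity.csv")
    dist_df <- do.call(rbind, lapply(names(distribution), function(nm) {
      d <- distribution[[nm]]
      data.frame(subset = nm, mean = d$mean, sd = d$sd,
                 ci_lo = d$ci_lo, ci_hi = d$ci_hi, n = d$n,
                 stringsAsFactors = FALSE)
    }))
    w(dist_df, "distribution.csv")
    w(base$spells, "spells_baseline.csv")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Validate pipeline input tables
#'
#' Structural and physical checks on county series and demography tables:
#' the daily ordering T_min <= T_avg <= T_max, dates inside the warm-season
#' window, nonnegative mortality rates, within-state population shares
#' summing to one, and duplicate county ids. Returns a line-level report;
#' an empty report means the inputs passed.
#'
#' @param series optional county series data frame (or CSV path).
#' @param demography optional county demography data frame (or CSV path).
#' @param share_tol tolerance on per-state share sums (default 1e-6).
#' @return data frame with `table`, `county_id`, `date`, `message`; zero
#'   rows when everything validates.
#' @export
validate_inputs <- function(series = NULL, demography = NULL, share_tol = 1e-6) {
  issues <- list()
  add <- function(table, county_id, date, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      table = table, county_id = county_id, date = date, message = message,
      stringsAsFactors = FALSE)

  if (is.character(series)) series <- read_series_csv(series)
  if (is.character(demography))
    demography <- utils::read.csv(demography, stringsAsFactors = FALSE)

  if (!is.null(series)) {
    bad <- which(!(series$tmin_c <= series$tavg_c & series$tavg_c <= series$tmax_c))
    for (i in bad)
      add("series", series$county_id[i], as.character(series$date[i]),
          "temperature ordering violated (requires tmin <= tavg <= tmax)")
    md <- format(as.Date(series$date), "%m-%d")
    out_season <- which(md < "05-01" | md > "09-30")
    for (i in out_season)
      add("series", series$county_id[i], as.character(series$date[i]),
          "date outside the 1 May - 30 Sep season window")
  }
  if (!is.null(demography)) {
    sums <- tapply(demography$state_share, demography$state_id, sum)
    for (s in names(sums)[abs(sums - 1) > share_tol])
      add("demography", s, NA_character_,
          sprintf("state shares sum to %.6f, not 1", sums[[s]]))
    for (i in which(demography$mortality_rate < 0))
      add("demography", demography$county_id[i], NA_character_,
          "negative mortality rate")
    dup <- unique(demography$county_id[duplicated(demography$county_id)])
    for (d in dup) add("demography", d, NA_character_, "duplicated county_id")
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(table = character(), county_id = character(),
                  date = character(), message = character(),
                  stringsAsFactors = FALSE)
}
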