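#' Build the full scenario factor grid of excess-mortality estimates
#'
#' Evaluates total excess deaths for every combination of emissions
#' scenario, calibration method, heat-wave definition, population
#' (migration) scenario, attributable-risk set, and projection year. With
#' the default levels (2 x 2 x 4 x 4 x 9 x 3) the grid has 1,728 cells.
#' Events detected under each (scenario, calibration, definition, year)
#' cell are combined with each AR set and population projection; a cell
#' with no events contributes zero deaths, but every detection combination
#' must have been evaluated - absent combinations are an error unless they
#' appear in `evaluated`.
#'
#' @param events event data frame carrying `rcp`, `calibration`,
#'   `definition`, `year` columns in addition to the event fields.
#' @param demography county data frame.
#' @param ar_sets AR sets from [sample_ar_sets()].
#' @param populations data frame `scenario`, `county_id`, `pop` covering
#'   every population scenario.
#' @param rcps,calibrations,hwds,years factor levels of the grid.
#' @param evaluated optional data frame (`rcp`, `calibration`,
#'   `definition`, `year`) listing detection runs that were executed;
#'   defaults to the combinations present in `events`. Any grid
#'   combination missing from it raises an error listing the absent cells.
#' @return data frame with one row per grid cell: `rcp`, `calibration`,
#'   `hwd`, `pop_scenario`, `ar_set`, `year`, `total_excess_deaths`.
#' @export
build_grid <- function(events, demography, ar_sets, populations,
                       rcps = c("rcp45", "rcp85"),
                       calibrations = c("fixed_radius", "nearest_k"),
                       hwds = hwd_kinds(),
                       years,
                       evaluated = NULL) {
  pop_scenarios <- unique(populations$scenario)
  if (is.null(evaluated) && nrow(events) > 0)
    evaluated <- unique(events[, c("rcp", "calibration", "definition", "year")])
  expected <- expand.grid(rcp = rcps, calibration = calibrations,
                          definition = hwds, year = years,
                          stringsAsFactors = FALSE)
  if (!is.null(evaluated)) {
    key <- function(d) paste(d$rcp, d$calibration, d$definition, d$year)
    absent <- expected[!key(expected) %in% key(evaluated), ]
    if (nrow(absent) > 0)
      stop("grid combinations never evaluated: ",
           paste(key(absent), collapse = "; "))
  }

  regions <- hw_regions()
  pop_by_sc <- lapply(split(populations, populations$scenario), function(p) {
    v <- p$pop; names(v) <- p$county_id; v
  })
  ev_key <- if (nrow(events) > 0)
    paste(events$rcp, events$calibration, events$definition, events$year)
  else character()

  cells <- vector("list", nrow(expected) * length(pop_scenarios) * nrow(ar_sets))
  k <- 0L
  for (i in seq_len(nrow(expected))) {
    kk <- paste(expected$rcp[i], expected$calibration[i],
                expected$definition[i], expected$year[i])
    ev <- events[ev_key == kk, , drop = FALSE]
    # per-county total heat-wave days for this detection cell
    L <- if (nrow(ev)) tapply(ev$length_days, ev$county_id, sum) else numeric()
    di <- match(names(L), demography$county_id)
    if (anyNA(di)) stop("events in counties without demography")
    rate <- demography$mortality_rate[di]
    reg <- demography$region[di]
    for (ps in pop_scenarios) {
      popv <- pop_by_sc[[ps]][names(L)]
      for (a in seq_len(nrow(ar_sets))) {
        ar <- unlist(ar_sets[a, regions])
        tot <- if (length(L)) sum(rate * popv * ar[reg] * as.numeric(L)) else 0
        k <- k + 1L
        cells[[k]] <- data.frame(
          rcp = expected$rcp[i], calibration = expected$calibration[i],
          hwd = expected$definition[i], pop_scenario = ps,
          ar_set = ar_sets$set_index[a], year = expected$year[i],
          total_excess_deaths = tot, stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, cells)
  rownames(grid) <- NULL
  n_expected <- length(rcps) * length(calibrations) * length(hwds) *
    length(pop_scenarios) * nrow(ar_sets) * length(years)
  stopifnot(nrow(grid) == n_expected)
  grid
}

#' Summarize a distribution of mortality estimates
#'
#' Mean, sample SD, empirical central confidence interval (percentiles with
#' linear interpolation), and cumulative probabilities `P(y < t)` at the
#' requested thresholds.
#'
#' @param values numeric vector of estimates (non-empty).
#' @param ci central interval coverage (default 0.95).
#' @param thresholds numeric vector of thresholds for cumulative
#'   probabilities (deaths/year).
#' @return list with `mean`, `sd`, `ci_lo`, `ci_hi`, `n`, and `cumulative`
#'   (named vector of `P(y < t)`).
#' @export
summarize_distribution <- function(values, ci = 0.95, thresholds = numeric(0)) {
  if (length(values) == 0) stop("no values to summarize")
  a <- (1 - ci) / 2
  cum <- vapply(thresholds, function(t) mean(values < t), 0)
  names(cum) <- as.character(thresholds)
  list(mean = mean(values),
       sd = if (length(values) > 1) sd(values) else 0,
       ci_lo = pct(values, a), ci_hi = pct(values, 1 - a),
       n = length(values), cumulative = cum)
}

#' First-order variance decomposition over a balanced factor grid
#'
#' Treats the scenario grid as a designed experiment with independent
#' discrete factors and computes, for each factor, the first-order
#' sensitivity index `S_i = V(E[y | x_i]) / V(y)`: the population variance
#' across factor levels of the conditional mean of the response, as a
#' fraction of the total population variance. On a balanced grid the `S_i`
#' of a purely additive response sum to one; the shortfall `1 - sum(S_i)`
#' is reported as the share attributable to factor interactions.
#'
#' @param grid data frame from [build_grid()] (or any balanced factor
#'   grid).
#' @param factors character vector of factor column names.
#' @param response response column name (default `"total_excess_deaths"`).
#' @return data frame with one row per factor (`factor`, `S_i`) plus a
#'   final `interactions` row carrying the residual share; attribute
#'   `"zero_variance"` is `TRUE` when the response is constant (all indices
#'   reported 0 with a warning).
#' @export
variance_decomposition <- function(grid,
                                   factors = c("rcp", "calibration", "hwd",
                                               "pop_scenario", "ar_set", "year"),
                                   response = "total_excess_deaths") {
  stopifnot(all(factors %in% names(grid)), response %in% names(grid))
  y <- grid[[response]]
  # balance: every level of every factor must appear equally often
  for (f in factors) {
    tab <- table(grid[[f]])
    if (length(unique(as.integer(tab))) != 1)
      stop("grid is not balanced in factor ", f)
  }
  vy <- pop_var(y)
  zero <- vy <= 0
  if (zero) {
    warning("total variance is zero; all sensitivity indices reported as 0")
    s <- rep(0, length(factors))
    resid <- 0
  } else {
    s <- vapply(factors, function(f) {
      m <- tapply(y, grid[[f]], mean)
      w <- as.integer(table(grid[[f]]))
      gm <- sum(w * m) / sum(w)
      sum(w * (m - gm)^2) / sum(w) / vy
    }, 0)
    resid <- 1 - sum(s)
  }
  out <- data.frame(factor = c(factors, "interactions"),
                    S_i = c(unname(s), resid), stringsAsFactors = FALSE)
  attr(out, "zero_variance") <- zero
  out
}
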