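#' Parameters of the synthetic climate generator
#'
#' Collects every knob of the synthetic weather model in one validated list.
#' The generator produces, for each county and warm season (1 May - 30 Sep),
#' a daily mean temperature built from a cosine seasonal cycle, a
#' latitudinal gradient, AR(1) day-to-day noise, and injected multi-day hot
#' spells; daily maxima and minima are fixed offsets from the mean, and dew
#' point is the mean minus a nonnegative spread so heat-index inputs always
#' exist.
#'
#' @param season_start,season_end month-day strings delimiting the analysis
#'   season (defaults 1 May and 30 Sep).
#' @param mean_tavg seasonal mean of daily average temperature at the
#'   domain's reference latitude, degrees C.
#' @param seasonal_amplitude half-range of the cosine seasonal cycle,
#'   degrees C (minimum at the season edges, maximum mid-season).
#' @param tmax_offset,tmin_offset offsets of daily maximum above and daily
#'   minimum below the daily mean, degrees C. Defaults 6.0 and 5.4, the
#'   mean summer differences the threshold floors are derived from.
#' @param lat_gradient warming per degree of latitude southward of the
#'   domain centre, degrees C per degree latitude.
#' @param dewpoint_spread nonnegative gap between daily mean temperature and
#'   dew point, degrees C (typical eastern-US summer dew-point depressions
#'   of the daily mean sit near 5-7).
#' @param noise_sd stationary standard deviation of the AR(1) daily noise,
#'   degrees C.
#' @param noise_autocorr lag-1 autocorrelation of the daily noise, in [0, 1).
#' @param warming_offset uniform warming added to every day of a generated
#'   period, degrees C; scenario runs use 2.0 (moderate-emission-like) and
#'   3.0 (high-emission-like).
#' @param hotspell_rate expected number of injected hot spells per county
#'   per season (Poisson), >= 0.
#' @param hotspell_count if non-NULL, exact number of spells injected per
#'   county-season, overriding `hotspell_rate`.
#' @param hotspell_bump additive temperature bump over spell days, degrees C.
#' @param hotspell_lengths integer vector of candidate spell lengths, drawn
#'   uniformly; default 2:7 spans the minimum-length criteria of all four
#'   heat-wave definitions.
#' @param station_bias multiplicative bias of the modeled temperatures
#'   relative to station truth (station value = model / bias + noise).
#' @param station_noise_sd standard deviation of station observation noise,
#'   degrees C.
#' @param station_fraction fraction of counties hosting stations, in (0, 1].
#' @param stations_per_county stations per selected county (>= 1).
#' @param seed integer RNG seed; identical parameters and seed reproduce the
#'   generated data exactly.
#'
#' @return an object of class `climate_params` (a validated list).
#' @export
climate_params <- function(season_start = "05-01", season_end = "09-30",
                           mean_tavg = 22.7, seasonal_amplitude = 4.5,
                           tmax_offset = 6.0, tmin_offset = 5.4,
                           lat_gradient = 1.0, dewpoint_spread = 6,
                           noise_sd = 3, noise_autocorr = 0.4,
                           warming_offset = 0,
                           hotspell_rate = 1.5, hotspell_count = NULL,
                           hotspell_bump = 4, hotspell_lengths = 2:7,
                           station_bias = 1.05, station_noise_sd = 0.5,
                           station_fraction = 0.4, stations_per_county = 1L,
                           seed = 1L) {
  p <- list(season_start = season_start, season_end = season_end,
            mean_tavg = mean_tavg, seasonal_amplitude = seasonal_amplitude,
            tmax_offset = tmax_offset, tmin_offset = tmin_offset,
            lat_gradient = lat_gradient, dewpoint_spread = dewpoint_spread,
            noise_sd = noise_sd, noise_autocorr = noise_autocorr,
            warming_offset = warming_offset,
            hotspell_rate = hotspell_rate, hotspell_count = hotspell_count,
            hotspell_bump = hotspell_bump, hotspell_lengths = as.integer(hotspell_lengths),
            station_bias = station_bias, station_noise_sd = station_noise_sd,
            station_fraction = station_fraction,
            stations_per_county = as.integer(stations_per_county),
            seed = as.integer(seed))
  if (p$noise_autocorr < 0 || p$noise_autocorr >= 1)
    stop("noise_autocorr must lie in [0, 1)")
  if (p$hotspell_rate < 0) stop("hotspell_rate must be >= 0")
  if (p$station_fraction <= 0 || p$station_fraction > 1)
    stop("station_fraction must lie in (0, 1]")
  if (p$tmax_offset < 0 || p$tmin_offset < 0)
    stop("diurnal offsets must be nonnegative")
  if (p$dewpoint_spread < 0) stop("dewpoint_spread must be nonnegative")
  if (p$noise_sd < 0 || p$station_noise_sd < 0) stop("noise sds must be nonnegative")
  if (p$station_bias <= 0) stop("station_bias must be positive")
  if (!is.null(p$hotspell_count) && p$hotspell_count < 0)
    stop("hotspell_count must be >= 0")
  class(p) <- "climate_params"
  p
}

#' Generate synthetic counties with demography
#'
#' Counties are placed on a jittered grid spanning roughly 10 degrees of
#' latitude, grouped into latitude-contiguous states, and states are
#' assigned to the three regions (Northeast at the top of the domain,
#' Midwest in the middle band, South at the bottom). Each county carries a
#' year-2000 population, its share of its state's population (shares sum to
#' one within every state), and a baseline non-accidental daily mortality
#' rate for non-heat-wave days.
#'
#' @param n_counties number of counties (>= `n_states`).
#' @param n_states number of states (>= 1).
#' @param seed integer RNG seed.
#' @return a data frame with columns `county_id`, `state_id`, `region`,
#'   `centroid_lat`, `centroid_lon`, `pop_2000`, `state_share`,
#'   `mortality_rate` (deaths per person per day).
#' @export
generate_counties <- function(n_counties, n_states, seed = 1L) {
  if (!is.numeric(n_counties) || n_counties < 1 || n_counties != round(n_counties))
    stop("n_counties must be a positive integer")
  if (!is.numeric(n_states) || n_states < 1 || n_states != round(n_states))
    stop("n_states must be a positive integer")
  if (n_counties < n_states) stop("n_counties must be >= n_states")
  n_counties <- as.integer(n_counties); n_states <- as.integer(n_states)

  set.seed(as.integer(seed))
  nx <- ceiling(sqrt(n_counties))
  ny <- ceiling(n_counties / nx)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))[seq_len(n_counties), ]
  # jittered grid at realistic county density (~0.5 deg between centroids,
  # as in the eastern US), growing with the county count up to a rectangle
  # spanning ~10 deg latitude x 12 deg longitude
  lat_span <- min(10, 0.50 * ny)
  lon_span <- min(12, 0.55 * nx)
  lat <- 28 + (g$iy - 0.5) / ny * lat_span + runif(n_counties, -0.45, 0.45) * lat_span / ny
  lon <- -95 + (g$ix - 0.5) / nx * lon_span + runif(n_counties, -0.45, 0.45) * lon_span / nx
  lat <- pmin(pmax(lat, -90), 90)
  lon <- pmin(pmax(lon, -180), 180)

  # states: contiguous latitude blocks of counties
  ord <- order(lat, lon)
  block <- rep(seq_len(n_states), length.out = 0L)
  sizes <- rep(n_counties %/% n_states, n_states)
  sizes[seq_len(n_counties %% n_states)] <- sizes[seq_len(n_counties %% n_states)] + 1L
  state_idx <- integer(n_counties)
  state_idx[ord] <- rep(seq_len(n_states), times = sizes)

  # regions: states ranked by mean latitude; top third Northeast, then
  # Midwest, bottom third South (ties impossible after jitter in practice)
  st_lat <- tapply(lat, state_idx, mean)
  rk <- rank(-st_lat, ties.method = "first")  # 1 = northernmost
  grp_sizes <- rep(n_states %/% 3, 3)
  grp_sizes[seq_len(n_states %% 3)] <- grp_sizes[seq_len(n_states %% 3)] + 1L
  region_of_state <- rep(hw_regions(), times = grp_sizes)[rk]

  pop <- rlnorm(n_counties, meanlog = log(8e4), sdlog = 1)
  share <- ave(pop, state_idx, FUN = function(x) x / sum(x))
  rate <- runif(n_counties, 2.0e-5, 2.8e-5)

  data.frame(
    county_id = sprintf("C%03d", seq_len(n_counties)),
    state_id = sprintf("S%02d", state_idx),
    region = region_of_state[state_idx],
    centroid_lat = lat, centroid_lon = lon,
    pop_2000 = pop, state_share = share, mortality_rate = rate,
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic daily temperature series
#'
#' For every county and every warm-season day of the requested years,
#' produces daily mean, maximum, minimum temperature and dew point from the
#' seasonal climatology plus AR(1) noise, a scenario warming offset, and
#' injected hot spells. The injected spells are returned in a truth log so
#' downstream detection can be validated against known events.
#'
#' @param counties county data frame from [generate_counties()].
#' @param params a [climate_params()] object; `params$seed` seeds the draw.
#' @param years integer vector of years to simulate.
#' @param warming_offset uniform offset, degrees C, added to every day
#'   (defaults to `params$warming_offset`); use 0 for the baseline period
#'   and a positive scenario offset for future periods.
#' @return a list with `series` (data frame: `county_id`, `date`, `year`,
#'   `tavg_c`, `tmax_c`, `tmin_c`, `dewpoint_c`) and `spells` (truth log:
#'   `county_id`, `year`, `start_date`, `length_days`, `bump_c`).
#' @export
generate_temperatures <- function(counties, params = climate_params(),
                                  years, warming_offset = params$warming_offset) {
  if (!inherits(params, "climate_params")) stop("params must be a climate_params object")
  if (is.null(counties) || nrow(counties) == 0) stop("county list must be non-empty")
  if (length(years) == 0) stop("period must be non-empty")
  years <- as.integer(years)

  set.seed(params$seed)
  lat_ref <- mean(counties$centroid_lat)
  series <- vector("list", nrow(counties) * length(years))
  spells <- list()
  k <- 0L
  for (ci in seq_len(nrow(counties))) {
    cid <- counties$county_id[ci]
    cmean <- params$mean_tavg +
      params$lat_gradient * (lat_ref - counties$centroid_lat[ci])
    for (yr in years) {
      d <- season_dates(yr, params$season_start, params$season_end)
      n <- length(d)
      s <- (seq_len(n) - 0.5) / n
      clim <- cmean - params$seasonal_amplitude * cos(2 * pi * s)

      # AR(1) noise with stationary sd = noise_sd
      e <- numeric(n)
      z <- rnorm(n)
      e[1] <- params$noise_sd * z[1]
      if (n > 1) {
        innov_sd <- params$noise_sd * sqrt(1 - params$noise_autocorr^2)
        for (t in 2:n) e[t] <- params$noise_autocorr * e[t - 1] + innov_sd * z[t]
      }
      tavg <- clim + warming_offset + e

      # injected hot spells
      n_sp <- if (!is.null(params$hotspell_count)) params$hotspell_count
              else rpois(1, params$hotspell_rate)
      if (n_sp > 0) {
        for (sp in seq_len(n_sp)) {
          len <- if (length(params$hotspell_lengths) == 1) params$hotspell_lengths
                 else sample(params$hotspell_lengths, 1)
          len <- min(len, n)
          start <- sample.int(n - len + 1L, 1)
          idx <- start:(start + len - 1L)
          tavg[idx] <- tavg[idx] + params$hotspell_bump
          spells[[length(spells) + 1L]] <- data.frame(
            county_id = cid, year = yr, start_date = d[start],
            length_days = len, bump_c = params$hotspell_bump,
            stringsAsFactors = FALSE)
        }
      }

      k <- k + 1L
      series[[k]] <- data.frame(
        county_id = cid, date = d, year = yr,
        tavg_c = tavg,
        tmax_c = tavg + params$tmax_offset,
        tmin_c = tavg - params$tmin_offset,
        dewpoint_c = tavg - params$dewpoint_spread,
        stringsAsFactors = FALSE)
    }
  }
  spells <- if (length(spells)) do.call(rbind, spells)
            else data.frame(county_id = character(), year = integer(),
                            start_date = as.Date(character()),
                            length_days = integer(), bump_c = numeric(),
                            stringsAsFactors = FALSE)
  list(series = do.call(rbind, series), spells = spells)
}

#' Generate synthetic station observations
#'
#' A seeded subset of counties (fraction `station_fraction`) hosts weather
#' stations; each station reports the county's modeled values divided by the
#' multiplicative `station_bias`, plus independent Gaussian observation
#' noise. This emulates a station archive used as the calibration reference
#' for biased model output: the downstream model/observation ratio recovers
#' `station_bias` exactly when the noise is zero.
#'
#' @param series model series data frame (the `series` element of
#'   [generate_temperatures()]).
#' @param counties county data frame (provides coordinates and the sampling
#'   frame).
#' @param params a [climate_params()] object.
#' @return data frame with `station_id`, `county_id`, `lat`, `lon`, `date`,
#'   `obs_tavg`, `obs_tmax`, `obs_tmin`.
#' @export
generate_stations <- function(series, counties, params = climate_params()) {
  if (!inherits(params, "climate_params")) stop("params must be a climate_params object")
  n <- nrow(counties)
  n_host <- max(1L, ceiling(params$station_fraction * n))
  set.seed(derive_seed(params$seed, 1L))
  hosts <- sort(sample(counties$county_id, n_host))

  out <- list()
  for (h in hosts) {
    ci <- match(h, counties$county_id)
    sub <- series[series$county_id == h, ]
    for (s in seq_len(params$stations_per_county)) {
      m <- nrow(sub)
      out[[length(out) + 1L]] <- data.frame(
        station_id = sprintf("%s-ST%02d", h, s),
        county_id = h,
        lat = counties$centroid_lat[ci] + runif(1, -0.05, 0.05),
        lon = counties$centroid_lon[ci] + runif(1, -0.05, 0.05),
        date = sub$date,
        obs_tavg = sub$tavg_c / params$station_bias + rnorm(m, 0, params$station_noise_sd),
        obs_tmax = sub$tmax_c / params$station_bias + rnorm(m, 0, params$station_noise_sd),
        obs_tmin = sub$tmin_c / params$station_bias + rnorm(m, 0, params$station_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate synthetic state population projections
#'
#' Mid-century state population projections under the four net-migration
#' assumptions, built as multiples of the year-2000 state populations. The
#' default multipliers decrease from the high-migration to the
#' zero-migration assumption, mirroring the ordering of published
#' cohort-component projections.
#'
#' @param counties county data frame from [generate_counties()].
#' @param multipliers named numeric vector of growth multipliers, one per
#'   migration scenario.
#' @return data frame with `state_id`, `scenario`, `pop_2050`.
#' @export
generate_state_projections <- function(counties,
                                       multipliers = c(high = 1.60,
                                                       constant_medium = 1.45,
                                                       low = 1.35,
                                                       zero = 1.15)) {
  st <- aggregate(pop_2000 ~ state_id, counties, sum)
  out <- do.call(rbind, lapply(names(multipliers), function(sc) {
    data.frame(state_id = st$state_id, scenario = sc,
               pop_2050 = st$pop_2000 * multipliers[[sc]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
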