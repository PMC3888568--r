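# Shared fixtures and independent oracles for the test suite.

# A small county set used across modules.
small_counties <- function(n = 12, states = 3, seed = 42) {
  generate_counties(n, states, seed)
}

# Climate parameters with all stochastic components switched off; any
# argument can still be overridden.
quiet_params <- function(...) {
  args <- list(noise_sd = 0, noise_autocorr = 0, hotspell_rate = 0,
               station_bias = 1, station_noise_sd = 0)
  do.call(climate_params, utils::modifyList(args, list(...)))
}

# Build a one-county series from a vector of daily mean temperatures,
# starting 1 May of `year`; tmax/tmin/dewpoint at fixed offsets.
make_series <- function(tavg, county_id = "C001", year = 2001,
                        tmax_offset = 6, tmin_offset = 5.4,
                        dewpoint_spread = 6) {
  d <- seq(as.Date(sprintf("%d-05-01", year)), by = "day",
           length.out = length(tavg))[seq_along(tavg)]
  data.frame(county_id = rep_len(county_id, length(tavg)), date = d,
             year = rep_len(year, length(tavg)),
             tavg_c = tavg, tmax_c = tavg + tmax_offset,
             tmin_c = tavg - tmin_offset, dewpoint_c = tavg - dewpoint_spread,
             stringsAsFactors = FALSE)
}

# A tmax-only series for Meehl-Tebaldi tests (other variables inert).
make_tmax_series <- function(tmax, county_id = "C001", year = 2001) {
  d <- seq(as.Date(sprintf("%d-05-01", year)), by = "day",
           length.out = length(tmax))
  data.frame(county_id = county_id, date = d, year = year,
             tavg_c = 0, tmax_c = tmax, tmin_c = 0, dewpoint_c = -10,
             stringsAsFactors = FALSE)
}

# Independent heat-index oracle: direct transcription of the NWS algorithm,
# kept separate from the package implementation.
oracle_heat_index_c <- function(temp_c, dewpoint_c) {
  es <- function(t) 6.112 * exp(17.62 * t / (243.12 + t))
  rh <- min(100, 100 * es(dewpoint_c) / es(temp_c))
  t <- temp_c * 9 / 5 + 32
  if (t <= 40) return((t - 32) * 5 / 9)
  hi <- 0.5 * (t + 61 + (t - 68) * 1.2 + rh * 0.094)
  if (hi >= 80) {
    hi <- -42.379 + 2.04901523 * t + 10.14333127 * rh - 0.22475541 * t * rh -
      6.83783e-3 * t^2 - 5.481717e-2 * rh^2 + 1.22874e-3 * t^2 * rh +
      8.5282e-4 * t * rh^2 - 1.99e-6 * t^2 * rh^2
    if (rh < 13 && t >= 80 && t <= 112)
      hi <- hi - ((13 - rh) / 4) * sqrt((17 - abs(t - 95)) / 17)
    if (rh > 85 && t >= 80 && t <= 87)
      hi <- hi + ((rh - 85) / 10) * ((87 - t) / 2)
  }
  (hi - 32) * 5 / 9
}

# Brute-force Meehl-Tebaldi oracle: enumerate every window of the series,
# keep those with all days > t2, at least `min_above` days > t1, and window
# mean > t1; within each maximal above-t2 run select the longest (earliest
# on ties). Returns a data.frame of (start, len) or a 0-row frame.
oracle_meehl_tebaldi <- function(x, t1, t2, min_above = 3) {
  n <- length(x)
  cands <- list()
  for (s in seq_len(n)) for (e in s:n) {
    w <- x[s:e]
    if (all(w > t2) && sum(w > t1) >= min_above && mean(w) > t1)
      cands[[length(cands) + 1L]] <- c(s, e - s + 1L)
  }
  if (!length(cands))
    return(data.frame(start = integer(), len = integer()))
  cd <- do.call(rbind, cands)
  # identify each candidate's maximal above-t2 run by expanding outward
  run_id <- vapply(cd[, 1], function(s) {
    i <- s
    while (i > 1 && x[i - 1] > t2) i <- i - 1
    i
  }, 0)
  out <- do.call(rbind, lapply(split(seq_len(nrow(cd)), run_id), function(idx) {
    sub <- cd[idx, , drop = FALSE]
    best <- sub[order(-sub[, 2], sub[, 1]), , drop = FALSE][1, ]
    data.frame(start = best[1], len = best[2])
  }))
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

# Haversine on a 6371-km sphere, written independently of the package.
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# Sort-based percentile with linear interpolation (type-7 convention),
# written out longhand as an oracle.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}
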