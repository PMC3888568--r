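#' Temperature unit conversions
#'
#' Convert between degrees Fahrenheit and degrees Celsius. All internal
#' computation in the package is in Celsius; Fahrenheit appears only at the
#' interface with the National Weather Service heat-index conventions, whose
#' operational thresholds are stated in Fahrenheit.
#'
#' @param x numeric vector of temperatures.
#' @return numeric vector of converted temperatures.
#' @examples
#' fahrenheit_to_celsius(80)  # 26.67
#' @export
fahrenheit_to_celsius <- function(x) (x - 32) * 5 / 9

#' @rdname fahrenheit_to_celsius
#' @export
celsius_to_fahrenheit <- function(x) x * 9 / 5 + 32

#' Derive a per-stage seed from a master seed
#'
#' Stages of the pipeline (county generation, baseline and future weather,
#' stations, attributable-risk sampling) each receive their own seed derived
#' from one master seed by a fixed counter scheme, so any stage can be rerun
#' in isolation and reproduce its output.
#'
#' @param master integer master seed.
#' @param stage integer stage counter (>= 0).
#' @return an integer seed strictly below 2^31 - 1.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(stage), length(stage) == 1L, stage >= 0)
  as.integer((abs(as.numeric(master)) + 7919 * as.numeric(stage)) %% 2147483647)
}

# Dates of the warm-season window (default 1 May - 30 Sep) for one year.
season_dates <- function(year, season_start = "05-01", season_end = "09-30") {
  seq(as.Date(sprintf("%04d-%s", year, season_start)),
      as.Date(sprintf("%04d-%s", year, season_end)), by = "day")
}

# Percentile with linear interpolation between order statistics (type 7);
# fixed package-wide for reproducibility.
pct <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE, na.rm = FALSE)

# Great-circle distances (km) between two sets of points, spherical Earth of
# radius 6371 km. `from` and `to` are data frames with centroid_lon /
# centroid_lat columns; returns a nrow(from) x nrow(to) matrix.
distance_matrix_km <- function(from, to) {
  p1 <- as.matrix(from[, c("centroid_lon", "centroid_lat")])
  p2 <- as.matrix(to[, c("centroid_lon", "centroid_lat")])
  geosphere::distm(p1, p2,
                   fun = function(a, b) geosphere::distHaversine(a, b, r = 6371000)) / 1000
}

# Population variance (denominator n); used in the variance decomposition so
# that main effects add exactly on balanced grids.
pop_var <- function(x) mean((x - mean(x))^2)

#' Region labels used by the attributable-risk model
#'
#' The study domain is partitioned into three regions, each with its own
#' attributable-risk range; every synthetic state is assigned to exactly one.
#'
#' @return character vector of the three region labels.
#' @export
hw_regions <- function() c("Northeast", "Midwest", "South")

#' Read and write county temperature series CSV
#'
#' County series are exchanged as plain CSV with columns `county_id`,
#' `date` (ISO-8601), `tavg_c`, `tmax_c`, `tmin_c`, `dewpoint_c`.
#'
#' @param series a county series data frame.
#' @param path file path.
#' @return `read_series_csv` returns the series data frame with `date` parsed
#'   as `Date` and a `year` column; `write_series_csv` returns `path`
#'   invisibly.
#' @export
write_series_csv <- function(series, path) {
  cols <- c("county_id", "date", "tavg_c", "tmax_c", "tmin_c", "dewpoint_c")
  stopifnot(all(cols %in% names(series)))
  out <- series[, cols]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  x$year <- as.integer(format(x$date, "%Y"))
  x
}
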