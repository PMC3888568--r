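#' Relative humidity from temperature and dew point
#'
#' Magnus saturation-vapor-pressure formula (6.112 hPa, 17.62, 243.12 C):
#' RH = 100 e_s(T_d)/e_s(T), capped at 100 for dew points at or above the
#' air temperature.
#'
#' @param temp_c air temperature, degrees C.
#' @param dewpoint_c dew point, degrees C.
#' @return relative humidity in percent (0-100).
#' @export
relative_humidity <- function(temp_c, dewpoint_c) {
  es <- function(t) 6.112 * exp(17.62 * t / (243.12 + t))
  pmin(100, 100 * es(dewpoint_c) / es(temp_c))
}

#' NWS heat index
#'
#' Operational National Weather Service heat index. Relative humidity is
#' derived from temperature and dew point via the Magnus formula; the index
#' is the simple Steadman average below its 80 F applicability bound, and
#' the Rothfusz regression with the published low-humidity (RH < 13%,
#' 80-112 F) and high-humidity (RH > 85%, 80-87 F) adjustments at or above
#' it. At or below 40 F the heat index is the temperature itself by
#' convention. Inputs and output are in degrees Celsius.
#'
#' @param temp_c air temperature, degrees C (must lie in (-90, 60)).
#' @param dewpoint_c dew point, degrees C (must not exceed `temp_c`).
#' @return heat index, degrees C, same length as the inputs.
#' @export
heat_index <- function(temp_c, dewpoint_c) {
  n <- max(length(temp_c), length(dewpoint_c))
  temp_c <- rep_len(temp_c, n); dewpoint_c <- rep_len(dewpoint_c, n)
  if (any(!is.finite(temp_c)) || any(!is.finite(dewpoint_c)))
    stop("temperature and dew point must be finite")
  if (any(temp_c < -90 | temp_c > 60))
    stop("temperature outside physical range (-90, 60) C")
  if (any(dewpoint_c > temp_c + 1e-9))
    stop("dew point must not exceed temperature")

  rh <- relative_humidity(temp_c, dewpoint_c)
  t_f <- celsius_to_fahrenheit(temp_c)

  hi <- 0.5 * (t_f + 61 + (t_f - 68) * 1.2 + rh * 0.094)
  hi[t_f <= 40] <- t_f[t_f <= 40]

  hot <- hi >= 80
  if (any(hot)) {
    t <- t_f[hot]; r <- rh[hot]
    reg <- -42.379 + 2.04901523 * t + 10.14333127 * r -
      0.22475541 * t * r - 6.83783e-3 * t^2 - 5.481717e-2 * r^2 +
      1.22874e-3 * t^2 * r + 8.5282e-4 * t * r^2 - 1.99e-6 * t^2 * r^2
    adj1 <- r < 13 & t >= 80 & t <= 112
    reg[adj1] <- reg[adj1] -
      ((13 - r[adj1]) / 4) * sqrt((17 - abs(t[adj1] - 95)) / 17)
    adj2 <- r > 85 & t >= 80 & t <= 87
    reg[adj2] <- reg[adj2] + ((r[adj2] - 85) / 10) * ((87 - t[adj2]) / 2)
    hi[hot] <- reg
  }
  fahrenheit_to_celsius(hi)
}
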