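#' Model-to-observation calibration ratios at station counties
#'
#' For every county hosting at least one station, computes the ratio of the
#' period mean of the modeled temperatures to the period mean of the station
#' observations, per variable (daily mean, maximum, minimum). Where a county
#' hosts several stations their observations are averaged per day first.
#' Before averaging, county-days whose observed value exceeds the
#' `exclusion_quantile` of that county's (or, optionally, the pooled)
#' observations are dropped, screening the hottest-tail days where model and
#' station records diverge most.
#'
#' @param model_series model county series data frame.
#' @param station_obs station observation data frame from
#'   [generate_stations()] or equivalent CSV.
#' @param exclusion_quantile observations above this quantile are excluded
#'   before the means (default 0.99).
#' @param quantile_scope `"per_county"` (default) computes the exclusion
#'   threshold per county and variable; `"pooled"` computes it once over all
#'   station observations per variable.
#' @return data frame with `county_id`, `ratio_tavg`, `ratio_tmax`,
#'   `ratio_tmin`, `n_support` (stations in the county), `method =
#'   "station"`; counties with no surviving days are omitted with a warning.
#' @export
compute_county_ratios <- function(model_series, station_obs,
                                  exclusion_quantile = 0.99,
                                  quantile_scope = c("per_county", "pooled")) {
  quantile_scope <- match.arg(quantile_scope)
  if (exclusion_quantile <= 0 || exclusion_quantile > 1)
    stop("exclusion_quantile must lie in (0, 1]")

  vars <- c(tavg = "obs_tavg", tmax = "obs_tmax", tmin = "obs_tmin")
  mvars <- c(tavg = "tavg_c", tmax = "tmax_c", tmin = "tmin_c")

  # average multiple stations per county-day
  n_stations <- tapply(station_obs$station_id, station_obs$county_id,
                       function(x) length(unique(x)))
  day_mean <- aggregate(station_obs[, vars],
                        by = list(county_id = station_obs$county_id,
                                  date = station_obs$date),
                        FUN = mean)
  merged <- merge(day_mean, model_series, by = c("county_id", "date"))
  if (nrow(merged) == 0) stop("model and observation series do not overlap")

  pooled_q <- vapply(vars, function(v) pct(merged[[v]], exclusion_quantile), 0)

  out <- lapply(split(merged, merged$county_id), function(sub) {
    r <- numeric(3); names(r) <- names(vars)
    for (v in names(vars)) {
      q <- if (quantile_scope == "pooled") pooled_q[[v]]
           else pct(sub[[vars[[v]]]], exclusion_quantile)
      keep <- sub[[vars[[v]]]] <= q
      if (!any(keep)) return(NULL)
      r[[v]] <- mean(sub[[mvars[[v]]]][keep]) / mean(sub[[vars[[v]]]][keep])
    }
    data.frame(county_id = sub$county_id[1],
               ratio_tavg = r[["tavg"]], ratio_tmax = r[["tmax"]],
               ratio_tmin = r[["tmin"]],
               n_support = as.integer(n_stations[[sub$county_id[1]]]),
               method = "station", stringsAsFactors = FALSE)
  })
  dropped <- names(out)[vapply(out, is.null, TRUE)]
  if (length(dropped))
    warning("counties with no surviving days after exclusion omitted: ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  res
}

#' Interpolate calibration ratios by fixed search radius
#'
#' Assigns every county the unweighted mean of all station-county ratios
#' whose centroids lie within `radius_km` (great-circle, spherical Earth of
#' radius 6371 km) of the county's centroid. The default 150-km radius is
#' chosen so that, in a realistically dense station network, every county
#' has at least one ratio in range; a county with an empty radius is an
#' error naming the offending counties.
#'
#' @param ratios station-county ratios from [compute_county_ratios()].
#' @param counties full county data frame (provides centroids).
#' @param radius_km search radius in kilometres (default 150).
#' @return data frame of per-county ratios with `n_support` (number of
#'   contributing station counties) and `method = "fixed_radius"`.
#' @export
interpolate_fixed_radius <- function(ratios, counties, radius_km = 150) {
  if (is.null(ratios) || nrow(ratios) == 0) stop("no station-county ratios available")
  st <- counties[match(ratios$county_id, counties$county_id), ]
  if (anyNA(st$county_id)) stop("ratios reference counties absent from the county table")
  d <- distance_matrix_km(counties, st)
  support <- d <= radius_km
  empty <- counties$county_id[rowSums(support) == 0]
  if (length(empty))
    stop("counties with no calibration ratio within ", radius_km, " km: ",
         paste(empty, collapse = ", "))
  agg <- function(col) vapply(seq_len(nrow(counties)),
                              function(i) mean(ratios[[col]][support[i, ]]), 0)
  data.frame(county_id = counties$county_id,
             ratio_tavg = agg("ratio_tavg"), ratio_tmax = agg("ratio_tmax"),
             ratio_tmin = agg("ratio_tmin"),
             n_support = as.integer(rowSums(support)),
             method = "fixed_radius", stringsAsFactors = FALSE)
}

#' Interpolate calibration ratios by k nearest station counties
#'
#' Assigns every county the unweighted mean of the `k` station-county
#' ratios closest to its centroid (great-circle distance); exact distance
#' ties are broken by ascending station county id.
#'
#' @inheritParams interpolate_fixed_radius
#' @param k number of nearest ratios to average (default 5); reduced with a
#'   warning when fewer station counties exist.
#' @return data frame of per-county ratios with `method = "nearest_k"`.
#' @export
interpolate_nearest_k <- function(ratios, counties, k = 5) {
  if (is.null(ratios) || nrow(ratios) == 0) stop("no station-county ratios available")
  if (k < 1) stop("k must be >= 1")
  if (nrow(ratios) < k) {
    warning("only ", nrow(ratios), " station-county ratios available; reducing k")
    k <- nrow(ratios)
  }
  st <- counties[match(ratios$county_id, counties$county_id), ]
  if (anyNA(st$county_id)) stop("ratios reference counties absent from the county table")
  # distances rounded to the millimetre so exact geometric ties resolve by
  # the county-id rule instead of floating-point noise
  d <- round(distance_matrix_km(counties, st), 6)
  pick <- function(i) order(d[i, ], ratios$county_id)[seq_len(k)]
  agg <- function(col) vapply(seq_len(nrow(counties)),
                              function(i) mean(ratios[[col]][pick(i)]), 0)
  data.frame(county_id = counties$county_id,
             ratio_tavg = agg("ratio_tavg"), ratio_tmax = agg("ratio_tmax"),
             ratio_tmin = agg("ratio_tmin"),
             n_support = as.integer(k),
             method = "nearest_k", stringsAsFactors = FALSE)
}

#' Apply calibration ratios to a county series
#'
#' Divides each temperature variable by its county's ratio, mapping the
#' modeled series onto the observation scale (the ratio being model over
#' observation). Dew point is divided by the daily-mean ratio so the
#' humidity input stays consistent with the calibrated mean temperature.
#' Day ordering and within-county rank order are preserved (division by a
#' positive constant is monotone).
#'
#' @param series model county series data frame.
#' @param ratios per-county ratios (every county in `series` must appear).
#' @return the calibrated series, same shape and row order as `series`.
#' @export
apply_calibration <- function(series, ratios) {
  idx <- match(series$county_id, ratios$county_id)
  if (anyNA(idx)) {
    missing <- unique(series$county_id[is.na(idx)])
    stop("no calibration ratio for counties: ", paste(missing, collapse = ", "))
  }
  if (any(ratios$ratio_tavg <= 0 | ratios$ratio_tmax <= 0 | ratios$ratio_tmin <= 0))
    stop("calibration ratios must be positive")
  out <- series
  out$tavg_c <- series$tavg_c / ratios$ratio_tavg[idx]
  out$tmax_c <- series$tmax_c / ratios$ratio_tmax[idx]
  out$tmin_c <- series$tmin_c / ratios$ratio_tmin[idx]
  if ("dewpoint_c" %in% names(series))
    out$dewpoint_c <- series$dewpoint_c / ratios$ratio_tavg[idx]
  out
}
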