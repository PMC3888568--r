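#' Heat-wave definition configuration
#'
#' Thresholds and run-length criteria for the four operational heat-wave
#' definitions:
#'
#' * `HWD_HI` - days whose daily low and high heat index are no less than
#'   the NWS thresholds of 26.7 C (80 F) and 40.5 C (105 F);
#' * `HWD_Tavg` - at least 2 consecutive days with daily mean temperature
#'   strictly above the baseline 95th percentile;
#' * `HWD_Tmax` - Meehl-Tebaldi: the longest window with at least 3 days
#'   above the baseline 97.5th percentile (T1), window mean above T1, and
#'   every day above the 81.5th percentile (T2);
#' * `HWD_Tmin` - at least 2 consecutive days with daily minimum strictly
#'   above the baseline 95th percentile.
#'
#' In mild counties the raw percentiles can sit at unremarkable
#' temperatures, so absolute floors are imposed: 26.7 C (80 F) on the daily
#' mean threshold, and 21.3 C and 32.7 C on the daily minimum and maximum
#' thresholds, derived from the 26.7 C floor by the mean summer offsets of
#' 5.4 C (mean minus minimum) and 6 C (maximum minus mean).
#'
#' @param hi_low_threshold,hi_high_threshold NWS heat-index thresholds for
#'   the daily low and high heat index, degrees C.
#' @param tavg_floor,tmin_floor,tmax_floor absolute minimum thresholds,
#'   degrees C; the T_max floor applies to the Meehl-Tebaldi T1 by default.
#' @param pct_tavg,pct_tmin percentile defining the daily mean / minimum
#'   thresholds (default 0.95).
#' @param pct_tmax_t1,pct_tmax_t2 Meehl-Tebaldi percentiles (defaults 0.975
#'   and 0.815).
#' @param min_len_tavg,min_len_tmin,min_len_tmax minimum event lengths in
#'   days (2, 2, 3).
#' @param min_len_hi minimum run length for heat-index events; the
#'   definition qualifies individual days, so single qualifying days count
#'   as length-1 events by default.
#' @param tmax_floor_applies `"t1"` (default) floors only the upper
#'   Meehl-Tebaldi threshold; `"both"` also floors T2 (then capped at T1).
#' @return an object of class `hwd_config`.
#' @export
hwd_config <- function(hi_low_threshold = 26.7, hi_high_threshold = 40.5,
                       tavg_floor = 26.7, tmin_floor = 21.3, tmax_floor = 32.7,
                       pct_tavg = 0.95, pct_tmin = 0.95,
                       pct_tmax_t1 = 0.975, pct_tmax_t2 = 0.815,
                       min_len_tavg = 2L, min_len_tmin = 2L, min_len_tmax = 3L,
                       min_len_hi = 1L,
                       tmax_floor_applies = c("t1", "both")) {
  cfg <- list(hi_low_threshold = hi_low_threshold,
              hi_high_threshold = hi_high_threshold,
              tavg_floor = tavg_floor, tmin_floor = tmin_floor,
              tmax_floor = tmax_floor,
              pct_tavg = pct_tavg, pct_tmin = pct_tmin,
              pct_tmax_t1 = pct_tmax_t1, pct_tmax_t2 = pct_tmax_t2,
              min_len_tavg = as.integer(min_len_tavg),
              min_len_tmin = as.integer(min_len_tmin),
              min_len_tmax = as.integer(min_len_tmax),
              min_len_hi = as.integer(min_len_hi),
              tmax_floor_applies = match.arg(tmax_floor_applies))
  pcts <- c(cfg$pct_tavg, cfg$pct_tmin, cfg$pct_tmax_t1, cfg$pct_tmax_t2)
  if (any(pcts <= 0 | pcts >= 1)) stop("percentiles must lie in (0, 1)")
  if (any(!is.finite(c(cfg$tavg_floor, cfg$tmin_floor, cfg$tmax_floor))))
    stop("floors must be finite")
  if (any(c(cfg$min_len_tavg, cfg$min_len_tmin, cfg$min_len_tmax, cfg$min_len_hi) < 1))
    stop("minimum lengths must be >= 1")
  class(cfg) <- "hwd_config"
  cfg
}

#' Definition labels of the four heat-wave metrics
#' @return character vector of the four definition names.
#' @export
hwd_kinds <- function() c("HWD_HI", "HWD_Tavg", "HWD_Tmax", "HWD_Tmin")

#' Baseline percentile thresholds per county
#'
#' Percentiles are computed per county over all baseline warm-season days
#' pooled across years (linear interpolation between order statistics), and
#' the absolute floors are applied as `max(percentile, floor)`. The
#' Meehl-Tebaldi lower threshold T2 is capped at T1 so the two-threshold
#' definition stays consistent after flooring.
#'
#' @param baseline_series calibrated baseline county series.
#' @param config an [hwd_config()] object.
#' @return data frame with `county_id`, `thr_tavg`, `thr_tmin`, `tmax_t1`,
#'   `tmax_t2`.
#' @export
compute_thresholds <- function(baseline_series, config = hwd_config()) {
  if (is.null(baseline_series) || nrow(baseline_series) == 0)
    stop("baseline series is empty")
  out <- lapply(split(baseline_series, baseline_series$county_id), function(sub) {
    if (nrow(sub) == 0) stop("county with no baseline days")
    t1 <- max(pct(sub$tmax_c, config$pct_tmax_t1), config$tmax_floor)
    t2 <- pct(sub$tmax_c, config$pct_tmax_t2)
    if (config$tmax_floor_applies == "both") t2 <- max(t2, config$tmax_floor)
    t2 <- min(t2, t1)
    data.frame(county_id = sub$county_id[1],
               thr_tavg = max(pct(sub$tavg_c, config$pct_tavg), config$tavg_floor),
               thr_tmin = max(pct(sub$tmin_c, config$pct_tmin), config$tmin_floor),
               tmax_t1 = t1, tmax_t2 = t2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# empty event frame with the canonical schema
empty_events <- function() {
  data.frame(county_id = character(), definition = character(),
             year = integer(), start_date = as.Date(character()),
             length_days = integer(), mean_intensity_c = numeric(),
             stringsAsFactors = FALSE)
}

# Group qualifying-day flags into maximal runs, breaking at calendar gaps
# (runs never span the end-of-season to start-of-season jump or a missing
# day). Returns events of length >= min_len.
runs_to_events <- function(flags, dates, values, min_len, county_id, definition) {
  stopifnot(!is.unsorted(dates))
  gap_grp <- cumsum(c(1L, as.integer(diff(dates) != 1)))
  r <- rle(paste0(gap_grp, "_", flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- flags[starts] & r$lengths >= min_len
  if (!any(keep)) return(empty_events())
  data.frame(
    county_id = county_id, definition = definition,
    year = as.integer(format(dates[starts[keep]], "%Y")),
    start_date = dates[starts[keep]],
    length_days = r$lengths[keep],
    mean_intensity_c = vapply(which(keep), function(i)
      mean(values[starts[i]:ends[i]]), 0),
    stringsAsFactors = FALSE)
}

#' Detect threshold-run heat waves (daily mean / daily minimum definitions)
#'
#' Finds maximal runs of consecutive warm-season days on which the chosen
#' variable is strictly greater than the county threshold, and keeps runs of
#' at least `min_len` days. Runs never cross the season gap or a year
#' boundary.
#'
#' @param series county series data frame, sorted by date within county.
#' @param variable `"tavg"` or `"tmin"` (selects `tavg_c` / `tmin_c`).
#' @param thresholds either a single number or a thresholds data frame from
#'   [compute_thresholds()] (the matching column is used).
#' @param min_len minimum run length in days.
#' @param definition label stored on the emitted events.
#' @return event data frame (`county_id`, `definition`, `year`,
#'   `start_date`, `length_days`, `mean_intensity_c`).
#' @export
detect_runs <- function(series, variable = c("tavg", "tmin"), thresholds,
                        min_len = 2L,
                        definition = paste0("HWD_T", match.arg(variable))) {
  variable <- match.arg(variable)
  col <- paste0(variable, "_c")
  thr_col <- paste0("thr_", variable)
  get_thr <- function(cid) {
    if (is.data.frame(thresholds)) {
      i <- match(cid, thresholds$county_id)
      if (is.na(i)) stop("no threshold for county ", cid)
      thresholds[[thr_col]][i]
    } else thresholds
  }
  out <- lapply(split(series, series$county_id), function(sub) {
    sub <- sub[order(sub$date), ]
    thr <- get_thr(sub$county_id[1])
    if (!is.finite(thr)) stop("threshold must be finite")
    runs_to_events(sub[[col]] > thr, sub$date, sub[[col]], min_len,
                   sub$county_id[1], definition)
  })
  res <- do.call(rbind, c(out, list(empty_events())))
  rownames(res) <- NULL
  res
}

#' Detect heat-index heat waves
#'
#' A day qualifies when its daily low heat index (from the daily minimum
#' temperature and dew point) is at least the 26.7 C (80 F) threshold and
#' its daily high heat index (from the daily maximum and dew point) is at
#' least 40.5 C (105 F). Consecutive qualifying days are grouped into one
#' event; single qualifying days are length-1 events under the default
#' configuration. Dew point is capped at the air temperature when
#' evaluating the index (saturation at the nighttime minimum).
#'
#' @param series county series with a `dewpoint_c` column.
#' @param config an [hwd_config()] object.
#' @return event data frame; `mean_intensity_c` is the mean daily high heat
#'   index over the event.
#' @export
detect_hi_days <- function(series, config = hwd_config()) {
  if (!"dewpoint_c" %in% names(series) || anyNA(series$dewpoint_c)) {
    bad <- if (!"dewpoint_c" %in% names(series)) "all rows"
           else paste(unique(series$county_id[is.na(series$dewpoint_c)]), collapse = ", ")
    stop("dew point missing for: ", bad)
  }
  hi_min <- heat_index(series$tmin_c, pmin(series$dewpoint_c, series$tmin_c))
  hi_max <- heat_index(series$tmax_c, pmin(series$dewpoint_c, series$tmax_c))
  qualify <- hi_min >= config$hi_low_threshold & hi_max >= config$hi_high_threshold
  df <- series
  df$.q <- qualify
  df$.him <- hi_max
  out <- lapply(split(df, df$county_id), function(sub) {
    sub <- sub[order(sub$date), ]
    runs_to_events(sub$.q, sub$date, sub$.him, config$min_len_hi,
                   sub$county_id[1], "HWD_HI")
  })
  res <- do.call(rbind, c(out, list(empty_events())))
  rownames(res) <- NULL
  res
}

# Meehl-Tebaldi search within one maximal run of days all above t2:
# the longest window with >= 3 days above t1 and window mean above t1
# (every day is above t2 by construction); earliest start wins ties.
mt_best_window <- function(x, t1, min_above = 3L) {
  n <- length(x)
  if (n < min_above) return(NULL)
  cs <- cumsum(x)
  ca <- cumsum(x > t1)
  for (len in n:min_above) {
    for (start in 1:(n - len + 1)) {
      end <- start + len - 1L
      n_above <- ca[end] - if (start > 1) ca[start - 1] else 0L
      if (n_above < min_above) next
      wmean <- (cs[end] - if (start > 1) cs[start - 1] else 0) / len
      if (wmean > t1) return(c(start = start, len = len))
    }
  }
  NULL
}

#' Detect Meehl-Tebaldi heat waves (daily maximum definition)
#'
#' Within each maximal run of consecutive days with daily maximum strictly
#' above the lower threshold T2, reports the longest window that contains
#' at least 3 days with daily maximum above the upper threshold T1 and
#' whose mean daily maximum exceeds T1; among equal-length windows the
#' earliest start wins. Events from different runs never overlap.
#'
#' @param series county series data frame.
#' @param thresholds thresholds data frame from [compute_thresholds()]
#'   (columns `tmax_t1`, `tmax_t2`).
#' @param config an [hwd_config()] object (supplies the 3-day criterion).
#' @return event data frame; `mean_intensity_c` is the mean daily maximum
#'   over the event.
#' @export
detect_meehl_tebaldi <- function(series, thresholds, config = hwd_config()) {
  out <- lapply(split(series, series$county_id), function(sub) {
    sub <- sub[order(sub$date), ]
    i <- match(sub$county_id[1], thresholds$county_id)
    if (is.na(i)) stop("no thresholds for county ", sub$county_id[1])
    t1 <- thresholds$tmax_t1[i]; t2 <- thresholds$tmax_t2[i]
    if (t2 > t1) stop("tmax_t2 exceeds tmax_t1 for county ", sub$county_id[1])
    x <- sub$tmax_c
    gap_grp <- cumsum(c(1L, as.integer(diff(sub$date) != 1)))
    above2 <- x > t2
    r <- rle(paste0(gap_grp, "_", above2))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- list()
    for (j in which(above2[starts])) {
      w <- mt_best_window(x[starts[j]:ends[j]], t1, config$min_len_tmax)
      if (is.null(w)) next
      s <- starts[j] + w[["start"]] - 1L
      e <- s + w[["len"]] - 1L
      ev[[length(ev) + 1L]] <- data.frame(
        county_id = sub$county_id[1], definition = "HWD_Tmax",
        year = as.integer(format(sub$date[s], "%Y")),
        start_date = sub$date[s], length_days = w[["len"]],
        mean_intensity_c = mean(x[s:e]), stringsAsFactors = FALSE)
    }
    do.call(rbind, c(ev, list(empty_events())))
  })
  res <- do.call(rbind, c(out, list(empty_events())))
  rownames(res) <- NULL
  res
}

#' Detect heat waves under one or all definitions
#'
#' Dispatcher over the four definitions.
#'
#' @param series calibrated county series.
#' @param thresholds thresholds data frame from [compute_thresholds()].
#' @param config an [hwd_config()] object.
#' @param kind one of `"HWD_HI"`, `"HWD_Tavg"`, `"HWD_Tmax"`, `"HWD_Tmin"`,
#'   or `"all"`.
#' @return event data frame with a `definition` column.
#' @export
detect_heatwaves <- function(series, thresholds, config = hwd_config(),
                             kind = "all") {
  kinds <- if (identical(kind, "all")) hwd_kinds() else match.arg(kind, hwd_kinds())
  out <- lapply(kinds, function(k) switch(
    k,
    HWD_HI = detect_hi_days(series, config),
    HWD_Tavg = detect_runs(series, "tavg", thresholds, config$min_len_tavg, "HWD_Tavg"),
    HWD_Tmin = detect_runs(series, "tmin", thresholds, config$min_len_tmin, "HWD_Tmin"),
    HWD_Tmax = detect_meehl_tebaldi(series, thresholds, config)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize heat-wave frequency and duration
#'
#' Frequency is events per year per county; duration statistics are the
#' mean and sample SD of event lengths. One row per definition (rows with
#' zero events report frequency 0 and `NA` durations so the four-definition
#' schema is always complete), plus a pooled `"all"` row.
#'
#' @param events event data frame.
#' @param n_years number of years the events were detected over.
#' @param n_counties number of counties screened.
#' @param definitions definition labels the summary must cover.
#' @return data frame with `definition`, `n_events`, `frequency`,
#'   `duration_mean`, `duration_sd`.
#' @export
summarize_events <- function(events, n_years, n_counties,
                             definitions = hwd_kinds()) {
  if (n_years < 1 || n_counties < 1) stop("n_years and n_counties must be >= 1")
  one <- function(lab, ev) {
    data.frame(definition = lab, n_events = nrow(ev),
               frequency = nrow(ev) / (n_years * n_counties),
               duration_mean = if (nrow(ev)) mean(ev$length_days) else NA_real_,
               duration_sd = if (nrow(ev) > 1) sd(ev$length_days) else NA_real_,
               stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(definitions, function(d)
    one(d, events[events$definition == d, , drop = FALSE])))
  rbind(per, one("all", events))
}
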