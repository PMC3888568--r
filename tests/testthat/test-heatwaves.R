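test_that("baseline thresholds apply percentiles and floors", {
  # constant 25 C series: percentile 25 < floor 26.7 -> floor wins
  s <- make_series(rep(25, 153))
  thr <- compute_thresholds(s)
  expect_equal(thr$thr_tavg, 26.7)
  expect_equal(thr$thr_tmin, max(25 - 5.4, 21.3))
  expect_equal(thr$tmax_t1, max(25 + 6, 32.7))

  # 100 distinct values: percentile matches the sort-based oracle
  set.seed(11)
  v <- sample(seq(20, 40, length.out = 100))
  s2 <- make_series(v)
  thr2 <- compute_thresholds(s2)
  expect_equal(thr2$thr_tavg, max(oracle_quantile7(v, 0.95), 26.7))
  expect_equal(thr2$tmax_t1, max(oracle_quantile7(v + 6, 0.975), 32.7))
  expect_equal(thr2$tmax_t2, min(oracle_quantile7(v + 6, 0.815), thr2$tmax_t1))

  # floor below the percentile leaves the percentile unchanged
  hot <- make_series(seq(30, 42, length.out = 153))
  thr3 <- compute_thresholds(hot)
  expect_equal(thr3$thr_tavg, oracle_quantile7(hot$tavg_c, 0.95))

  # flooring T2 as well keeps t2 <= t1
  thr4 <- compute_thresholds(make_series(rep(20, 153)),
                             hwd_config(tmax_floor_applies = "both"))
  expect_equal(thr4$tmax_t2, thr4$tmax_t1)

  expect_error(compute_thresholds(make_series(numeric(0))), "empty")
})

test_that("run detection enumerates maximal runs above threshold", {
  s <- make_series(c(27, 28, 26, 29, 30, 31))
  ev <- detect_runs(s, "tavg", 26.7, min_len = 2)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$length_days, c(2L, 3L))
  expect_equal(ev$start_date, as.Date(c("2001-05-01", "2001-05-04")))
  expect_equal(ev$mean_intensity_c, c(27.5, 30))

  # all below: nothing
  expect_equal(nrow(detect_runs(make_series(rep(20, 10)), "tavg", 26.7, 2)), 0L)
  # single isolated hot day fails min_len 2
  expect_equal(nrow(detect_runs(make_series(c(20, 30, 20)), "tavg", 26.7, 2)), 0L)
  # strict inequality: equal to threshold does not qualify
  expect_equal(nrow(detect_runs(make_series(rep(26.7, 5)), "tavg", 26.7, 2)), 0L)

  # runs never span the season gap between years
  s2 <- rbind(make_series(rep(30, 3), year = 2001),
              make_series(rep(30, 3), year = 2002))
  ev2 <- detect_runs(s2, "tavg", 26.7, 2)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$year, c(2001L, 2002L))
})

test_that("run detection matches manual enumeration on random series", {
  set.seed(202)
  for (rep in 1:25) {
    v <- round(runif(30, 24, 32), 1)
    ev <- detect_runs(make_series(v), "tavg", 27, min_len = 2)
    # oracle: scan for maximal runs by hand
    above <- v > 27
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    want <- data.frame(start = starts[runs$values & runs$lengths >= 2],
                       len = runs$lengths[runs$values & runs$lengths >= 2])
    expect_equal(nrow(ev), nrow(want))
    if (nrow(want)) {
      expect_equal(as.integer(ev$start_date - as.Date("2001-05-01")) + 1,
                   want$start)
      expect_equal(ev$length_days, want$len)
    }
  }
})

test_that("heat-index days qualify on both NWS thresholds and group into events", {
  cfg <- hwd_config()
  # hot humid stretch: 3 qualifying days bracketed by cool days
  tavg <- c(25, 25, 34, 34, 34, 25, 25)
  s <- make_series(tavg, dewpoint_spread = 4)
  ev <- detect_hi_days(s, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$length_days, 3L)
  expect_equal(ev$definition, "HWD_HI")

  # a cool or dry day fails the high threshold
  mild <- make_series(rep(28, 5), dewpoint_spread = 12)
  expect_equal(nrow(detect_hi_days(mild, cfg)), 0L)

  # missing dew point is an error naming the county
  bad <- s; bad$dewpoint_c[2] <- NA
  expect_error(detect_hi_days(bad, cfg), "C001")

  # qualifying flags match an independent day-by-day re-evaluation
  set.seed(77)
  tavg <- runif(1000, 20, 38)
  spread <- runif(1000, 2, 10)
  days <- make_series(tavg, dewpoint_spread = 0)
  days$dewpoint_c <- tavg - spread
  ev_all <- detect_hi_days(days, cfg)
  flagged <- rep(FALSE, 1000)
  for (e in seq_len(nrow(ev_all))) {
    i0 <- as.integer(ev_all$start_date[e] - days$date[1]) + 1
    flagged[i0:(i0 + ev_all$length_days[e] - 1)] <- TRUE
  }
  want <- vapply(seq_len(1000), function(i) {
    lo <- oracle_heat_index_c(days$tmin_c[i], min(days$dewpoint_c[i], days$tmin_c[i]))
    hi <- oracle_heat_index_c(days$tmax_c[i], min(days$dewpoint_c[i], days$tmax_c[i]))
    lo >= 26.7 && hi >= 40.5
  }, TRUE)
  expect_equal(flagged, want)
})

test_that("Meehl-Tebaldi detection handles the minimal cases", {
  thr <- data.frame(county_id = "C001", thr_tavg = 99, thr_tmin = 99,
                    tmax_t1 = 35, tmax_t2 = 30, stringsAsFactors = FALSE)
  # 3 days above T1 bracketed by sub-T2 days: one event of length 3
  s <- make_tmax_series(c(25, 36, 36, 36, 25))
  ev <- detect_meehl_tebaldi(s, thr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$length_days, 3L)
  expect_equal(ev$start_date, as.Date("2001-05-02"))

  # only 2 days above T1: criterion (a) fails
  expect_equal(nrow(detect_meehl_tebaldi(
    make_tmax_series(c(25, 36, 36, 25)), thr)), 0L)

  # above-T2 shoulder days join when the window mean stays above T1
  ev2 <- detect_meehl_tebaldi(make_tmax_series(c(25, 31, 40, 40, 40, 31, 25)), thr)
  expect_equal(ev2$length_days, 5L)
  # but drop off when they drag the mean to T1 or below
  ev3 <- detect_meehl_tebaldi(make_tmax_series(c(25, 31, 36, 36, 36, 31, 25)), thr)
  expect_equal(ev3$length_days, 3L)
  expect_equal(ev3$start_date, as.Date("2001-05-03"))
})

test_that("Meehl-Tebaldi equals brute-force window enumeration on random series", {
  thr <- data.frame(county_id = "C001", thr_tavg = 99, thr_tmin = 99,
                    tmax_t1 = 34, tmax_t2 = 30, stringsAsFactors = FALSE)
  set.seed(313)
  for (rep in 1:60) {
    v <- sample(c(25, 32, 38), 15, replace = TRUE)
    ev <- detect_meehl_tebaldi(make_tmax_series(v), thr)
    want <- oracle_meehl_tebaldi(v, t1 = 34, t2 = 30)
    expect_equal(nrow(ev), nrow(want))
    if (nrow(want)) {
      expect_equal(as.integer(ev$start_date - as.Date("2001-05-01")) + 1,
                   want$start)
      expect_equal(ev$length_days, as.integer(want$len))
    }
  }
})

test_that("every emitted event re-verifies its definition's criteria", {
  cty <- small_counties(8, 2)
  p <- climate_params(seed = 19)
  x <- generate_temperatures(cty, p, 2001:2002, warming_offset = 2)
  thr <- compute_thresholds(x$series)
  cfg <- hwd_config()
  ev <- detect_heatwaves(x$series, thr, cfg)
  expect_gt(nrow(ev), 0)

  by_day <- split(x$series, x$series$county_id)
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    sub <- by_day[[e$county_id]]
    idx <- which(sub$date >= e$start_date &
                   sub$date <= e$start_date + e$length_days - 1)
    expect_equal(length(idx), e$length_days)
    th <- thr[thr$county_id == e$county_id, ]
    ok <- switch(e$definition,
      HWD_Tavg = all(sub$tavg_c[idx] > th$thr_tavg) && e$length_days >= 2,
      HWD_Tmin = all(sub$tmin_c[idx] > th$thr_tmin) && e$length_days >= 2,
      HWD_Tmax = all(sub$tmax_c[idx] > th$tmax_t2) &&
        sum(sub$tmax_c[idx] > th$tmax_t1) >= 3 &&
        mean(sub$tmax_c[idx]) > th$tmax_t1,
      HWD_HI = all(vapply(idx, function(j) {
        lo <- oracle_heat_index_c(sub$tmin_c[j],
                                  min(sub$dewpoint_c[j], sub$tmin_c[j]))
        hi <- oracle_heat_index_c(sub$tmax_c[j],
                                  min(sub$dewpoint_c[j], sub$tmax_c[j]))
        lo >= 26.7 && hi >= 40.5
      }, TRUE)))
    expect_true(ok, info = paste(e$definition, e$county_id, e$start_date))
  }

  # non-overlap within (county, definition, year)
  key <- paste(ev$county_id, ev$definition, ev$year)
  for (k in unique(key)) {
    sub <- ev[key == k, ]
    sub <- sub[order(sub$start_date), ]
    if (nrow(sub) > 1) {
      gaps <- as.integer(sub$start_date[-1] -
                           (sub$start_date[-nrow(sub)] +
                              sub$length_days[-nrow(sub)] - 1))
      expect_true(all(gaps >= 1))
    }
  }
})

test_that("warming and floors move event counts monotonically", {
  cty <- small_counties(6, 2)
  p <- climate_params(seed = 23)
  x <- generate_temperatures(cty, p, 2001)
  thr <- compute_thresholds(x$series)

  # uniform warming never decreases qualifying days for threshold definitions
  warmer <- x$series
  warmer$tavg_c <- warmer$tavg_c + 1
  warmer$tmin_c <- warmer$tmin_c + 1
  n_days <- function(s) sum(s$tavg_c > thr$thr_tavg[match(s$county_id, thr$county_id)])
  expect_gte(n_days(warmer), n_days(x$series))

  # raising a floor weakly decreases event counts
  lo <- detect_runs(x$series, "tavg",
                    compute_thresholds(x$series, hwd_config(tavg_floor = 20)), 2)
  hi <- detect_runs(x$series, "tavg",
                    compute_thresholds(x$series, hwd_config(tavg_floor = 30)), 2)
  expect_lte(nrow(hi), nrow(lo))
})

test_that("event summaries reduce to hand arithmetic with a fixed schema", {
  ev <- data.frame(county_id = "C001", definition = "HWD_Tavg",
                   year = c(2001L, 2001L, 2002L),
                   start_date = as.Date(c("2001-06-01", "2001-07-01", "2002-06-01")),
                   length_days = c(2L, 3L, 4L), mean_intensity_c = 30,
                   stringsAsFactors = FALSE)
  s <- summarize_events(ev, n_years = 2, n_counties = 1)
  row <- s[s$definition == "HWD_Tavg", ]
  expect_equal(row$frequency, 1.5)
  expect_equal(row$duration_mean, 3.0)
  expect_equal(row$duration_sd, 1.0)

  # schema always carries the four definition rows plus the pooled row
  expect_setequal(s$definition, c(hwd_kinds(), "all"))
  empty <- summarize_events(ev[0, ], 2, 1)
  expect_equal(empty$frequency, rep(0, 5))
  expect_true(all(is.na(empty$duration_mean)))
  expect_error(summarize_events(ev, 0, 1), ">= 1")
})
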