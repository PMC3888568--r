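test_that("county ratios reduce to hand arithmetic", {
  # identity: observations equal model -> ratio 1 everywhere
  cty <- small_counties(6, 2)
  p <- quiet_params(station_fraction = 1)
  x <- generate_temperatures(cty, p, 2001)
  st <- generate_stations(x$series, cty, p)
  r <- compute_county_ratios(x$series, st)
  expect_equal(r$ratio_tavg, rep(1, nrow(cty)))
  expect_equal(r$ratio_tmax, rep(1, nrow(cty)))
  expect_equal(r$ratio_tmin, rep(1, nrow(cty)))

  # two stations averaged per day before the ratio: 30 / mean(25, 20)
  d <- seq(as.Date("2001-05-01"), by = "day", length.out = 20)
  model <- data.frame(county_id = "C001", date = d, tavg_c = 30,
                      tmax_c = 30, tmin_c = 30, stringsAsFactors = FALSE)
  obs <- rbind(
    data.frame(station_id = "A", county_id = "C001", lat = 0, lon = 0,
               date = d, obs_tavg = 25, obs_tmax = 25, obs_tmin = 25),
    data.frame(station_id = "B", county_id = "C001", lat = 0, lon = 0,
               date = d, obs_tavg = 20, obs_tmax = 20, obs_tmin = 20))
  r2 <- compute_county_ratios(model, obs)
  expect_equal(r2$ratio_tavg, 30 / 22.5, tolerance = 1e-12)
  expect_equal(r2$n_support, 2L)

  # counties without stations are absent from the output
  p2 <- quiet_params(station_fraction = 0.5)
  st2 <- generate_stations(x$series, cty, p2)
  r3 <- compute_county_ratios(x$series, st2)
  expect_lt(nrow(r3), nrow(cty))
  expect_true(all(r3$county_id %in% unique(st2$county_id)))
})

test_that("hot-tail exclusion drops observed days above the quantile", {
  # 100 days, one extreme observed day; with q = 0.99 that day is excluded
  d <- seq(as.Date("2001-05-01"), by = "day", length.out = 100)
  obs_v <- c(rep(20, 99), 40)
  model <- data.frame(county_id = "C001", date = d, tavg_c = 25,
                      tmax_c = 25, tmin_c = 25, stringsAsFactors = FALSE)
  obs <- data.frame(station_id = "A", county_id = "C001", lat = 0, lon = 0,
                    date = d, obs_tavg = obs_v, obs_tmax = obs_v,
                    obs_tmin = obs_v, stringsAsFactors = FALSE)
  r <- compute_county_ratios(model, obs, exclusion_quantile = 0.99)
  expect_equal(r$ratio_tavg, 25 / 20, tolerance = 1e-12)
  # with no exclusion the extreme day dilutes the mean
  r_all <- compute_county_ratios(model, obs, exclusion_quantile = 1)
  expect_equal(r_all$ratio_tavg, 25 / mean(obs_v), tolerance = 1e-12)
})

test_that("fixed-radius interpolation matches brute-force distances", {
  cty <- generate_counties(50, 5, seed = 31)
  p <- quiet_params(station_fraction = 0.3, station_bias = 1.08)
  x <- generate_temperatures(cty, p, 2001)
  st <- generate_stations(x$series, cty, p)
  ratios <- compute_county_ratios(x$series, st)
  out <- interpolate_fixed_radius(ratios, cty, radius_km = 150)

  st_cty <- cty[match(ratios$county_id, cty$county_id), ]
  for (i in seq_len(nrow(cty))) {
    dd <- oracle_haversine_km(cty$centroid_lat[i], cty$centroid_lon[i],
                              st_cty$centroid_lat, st_cty$centroid_lon)
    sel <- dd <= 150
    expect_equal(out$ratio_tavg[i], mean(ratios$ratio_tavg[sel]),
                 tolerance = 1e-9)
    expect_equal(out$n_support[i], sum(sel))
  }

  # single supporting ratio propagates everywhere in range
  one <- ratios[1, ]
  near <- cty[oracle_haversine_km(cty$centroid_lat, cty$centroid_lon,
                                  st_cty$centroid_lat[1],
                                  st_cty$centroid_lon[1]) <= 150, ]
  out1 <- interpolate_fixed_radius(one, near, radius_km = 150)
  expect_true(all(out1$ratio_tavg == one$ratio_tavg))
})

test_that("an out-of-radius county is an error naming the county", {
  cty <- data.frame(county_id = c("C001", "C002"),
                    state_id = "S01", region = "South",
                    centroid_lat = c(30, 32), centroid_lon = c(-90, -90),
                    stringsAsFactors = FALSE)
  ratios <- data.frame(county_id = "C001", ratio_tavg = 1.05,
                       ratio_tmax = 1.05, ratio_tmin = 1.05,
                       n_support = 1L, method = "station",
                       stringsAsFactors = FALSE)
  # C002 is ~222 km from the only ratio
  expect_error(interpolate_fixed_radius(ratios, cty, radius_km = 150), "C002")
  expect_silent(interpolate_fixed_radius(ratios, cty, radius_km = 250))
})

test_that("nearest-k interpolation matches an exhaustive distance sort", {
  cty <- generate_counties(50, 5, seed = 77)
  p <- quiet_params(station_fraction = 0.2, station_bias = 1.03)
  x <- generate_temperatures(cty, p, 2001)
  st <- generate_stations(x$series, cty, p)
  ratios <- compute_county_ratios(x$series, st)
  expect_gte(nrow(ratios), 6)
  out <- interpolate_nearest_k(ratios, cty, k = 5)

  st_cty <- cty[match(ratios$county_id, cty$county_id), ]
  for (i in seq_len(nrow(cty))) {
    dd <- oracle_haversine_km(cty$centroid_lat[i], cty$centroid_lon[i],
                              st_cty$centroid_lat, st_cty$centroid_lon)
    sel <- order(dd, ratios$county_id)[1:5]
    expect_equal(out$ratio_tavg[i], mean(ratios$ratio_tavg[sel]),
                 tolerance = 1e-9)
  }

  # k equal to the pool size gives the global mean everywhere
  out_all <- interpolate_nearest_k(ratios, cty, k = nrow(ratios))
  expect_true(all(abs(out_all$ratio_tavg - mean(ratios$ratio_tavg)) < 1e-12))

  # fewer ratios than k: warn and reduce
  expect_warning(interpolate_nearest_k(ratios[1:3, ], cty, k = 5), "reducing")
  expect_error(interpolate_nearest_k(ratios[0, ], cty, k = 5), "no station")
})

test_that("equidistant candidates break ties by ascending county id", {
  cty <- data.frame(county_id = c("C001", "C002", "C003"),
                    state_id = "S01", region = "South",
                    centroid_lat = c(30, 31, 29), centroid_lon = -90,
                    stringsAsFactors = FALSE)
  ratios <- data.frame(county_id = c("C002", "C003"),
                       ratio_tavg = c(1.2, 1.4), ratio_tmax = c(1.2, 1.4),
                       ratio_tmin = c(1.2, 1.4), n_support = 1L,
                       method = "station", stringsAsFactors = FALSE)
  # C002 and C003 are both exactly 1 degree from C001; k = 1 picks C002
  out <- interpolate_nearest_k(ratios, cty, k = 1)
  expect_equal(out$ratio_tavg[out$county_id == "C001"], 1.2)
})

test_that("applying calibration is exact, order-preserving division", {
  cty <- small_counties(4, 2)
  p <- quiet_params()
  x <- generate_temperatures(cty, p, 2001)
  ident <- data.frame(county_id = cty$county_id, ratio_tavg = 1,
                      ratio_tmax = 1, ratio_tmin = 1, n_support = 1L,
                      method = "fixed_radius", stringsAsFactors = FALSE)
  expect_equal(apply_calibration(x$series, ident), x$series)

  r <- ident; r$ratio_tavg <- 1.25
  one_day <- make_series(30)[1, ]
  one_day$county_id <- cty$county_id[1]
  expect_equal(apply_calibration(one_day, r)$tavg_c, 24)

  # rank order within county preserved
  pn <- climate_params(seed = 8)
  xn <- generate_temperatures(cty, pn, 2001)
  rr <- ident; rr$ratio_tavg <- runif(nrow(cty), 0.9, 1.1)
  cal <- apply_calibration(xn$series, rr)
  for (cid in cty$county_id) {
    a <- xn$series$tavg_c[xn$series$county_id == cid]
    b <- cal$tavg_c[cal$county_id == cid]
    expect_equal(cor(a, b, method = "spearman"), 1)
  }

  expect_error(apply_calibration(x$series, ident[-1, ]),
               x$series$county_id[1])
})

test_that("a constant multiplicative bias round-trips through calibration", {
  cty <- small_counties(10, 2)
  p <- quiet_params(station_fraction = 0.5, station_bias = 1.05)
  x <- generate_temperatures(cty, p, 2001)
  st <- generate_stations(x$series, cty, p)
  ratios <- compute_county_ratios(x$series, st)
  # bias recovered to near machine precision at station counties
  expect_true(all(abs(ratios$ratio_tavg - 1.05) < 1e-9))
  expect_true(all(abs(ratios$ratio_tmax - 1.05) < 1e-9))

  # interpolation keeps the constant field constant; calibrated model
  # equals observation-scale truth
  full <- interpolate_fixed_radius(ratios, cty, radius_km = 300)
  cal <- apply_calibration(x$series, full)
  expect_true(all(abs(cal$tavg_c - x$series$tavg_c / 1.05) < 1e-6))
})
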