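test_that("identical spec and seed reproduce the series bit for bit", {
  spec <- climate_spec(seed = 7)
  w1 <- generate_weather(spec, 1)
  w2 <- generate_weather(spec, 1)
  expect_identical(w1, w2)
  w3 <- generate_weather(climate_spec(seed = 8), 1)
  expect_false(identical(w1$tav, w3$tav))
})

test_that("the warming offset shifts every temperature by exactly delta_T", {
  base <- climate_spec(seed = 3, delta_T = 0)
  warm <- climate_spec(seed = 3, delta_T = 2)
  w0 <- generate_weather(base, 1)
  w2 <- generate_weather(warm, 1)
  expect_equal(w2$tav - w0$tav, rep(2, nrow(w0)))
  expect_equal(w2$tmin - w0$tmin, rep(2, nrow(w0)))
  expect_equal(w2$tmax - w0$tmax, rep(2, nrow(w0)))
  # precipitation and radiation untouched by the offset
  expect_identical(w0$precip, w2$precip)
  expect_identical(w0$srad, w2$srad)
})

test_that("wet-day frequency matches the chain's stationary probability", {
  # with persistence p11 = 0.3 and target frequency 0.3 the dry-to-wet
  # probability solves to 0.3 as well (an independence chain), so the
  # stationary frequency is exactly 0.3
  spec <- climate_spec(seed = 1, wet_day_prob = 0.3, wet_persistence = 0.3)
  w <- generate_weather(spec, 30)
  expect_lt(abs(mean(w$precip > 0) - 0.3), 0.02)
})

test_that("temperature ordering and positivity invariants hold over random specs", {
  set.seed(42)
  for (k in 1:8) {
    spec <- climate_spec(latitude = runif(1, 35, 60),
                         annual_mean_temp = runif(1, 3, 18),
                         seasonal_amplitude = runif(1, 5, 12),
                         diurnal_range = runif(1, 4, 14),
                         anomaly_sd = runif(1, 1, 5),
                         anomaly_autocorr = runif(1, 0, 0.9),
                         wet_day_prob = runif(1, 0.1, 0.5),
                         wet_persistence = runif(1, 0.3, 0.8),
                         seed = k)
    w <- generate_weather(spec, 2)
    expect_true(all(w$tmin <= w$tav & w$tav <= w$tmax))
    expect_true(all(w$precip >= 0))
    expect_true(all(w$rh >= 0 & w$rh <= 100))
    expect_true(all(w$wind10 >= 0))
    expect_true(all(w$srad >= 0))
    expect_true(all(w$co2 > 0))
    expect_silent(validate_daily_weather(w))
  }
})

test_that("precip_factor scales every wet-day amount exactly", {
  s1 <- climate_spec(seed = 11, precip_factor = 1)
  s3 <- climate_spec(seed = 11, precip_factor = 3)
  w1 <- generate_weather(s1, 2)
  w3 <- generate_weather(s3, 2)
  expect_identical(w1$precip > 0, w3$precip > 0)
  wet <- w1$precip > 0
  expect_equal(w3$precip[wet], 3 * w1$precip[wet])
})

test_that("CO2 follows the linear annual trajectory, repeated daily", {
  spec <- climate_spec(seed = 2, co2_start = 400, co2_trend = 2.5)
  w <- generate_weather(spec, 3, start_year = 2030)
  yr <- as.integer(format(w$date, "%Y"))
  expect_equal(unique(w$co2[yr == 2030]), 400)
  expect_equal(unique(w$co2[yr == 2032]), 405)
})

test_that("leap days are generated and the calendar is contiguous", {
  w <- generate_weather(climate_spec(seed = 5), 1, start_year = 2004)
  expect_equal(nrow(w), 366)
  expect_true(as.Date("2004-02-29") %in% w$date)
})

test_that("ensembles have distinct members, stable order, and a degenerate single member", {
  spec <- climate_spec(seed = 9)
  ens <- generate_ensemble(spec, 5, 2)
  expect_length(ens, 5)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(identical(ens[[i]]$tav, ens[[j]]$tav))
  }
  ens2 <- generate_ensemble(spec, 5, 2)
  expect_identical(ens, ens2)
  one <- generate_ensemble(spec, 1, 2)
  expect_identical(one[[1]], generate_weather(spec, 2))
  expect_error(generate_ensemble(spec, 0, 2), "n_members")
})

test_that("a uniform +2 warming raises every member's multi-year mean tav", {
  base <- climate_spec(seed = 4, delta_T = 0)
  warm <- climate_spec(seed = 4, delta_T = 2)
  e0 <- generate_ensemble(base, 5, 5)
  e2 <- generate_ensemble(warm, 5, 5)
  for (m in 1:5) expect_gt(mean(e2[[m]]$tav), mean(e0[[m]]$tav))
})

test_that("invalid spec fields are rejected with the field named", {
  expect_error(climate_spec(wet_day_prob = 1.4), "wet_day_prob")
  expect_error(climate_spec(anomaly_sd = -1), "anomaly_sd")
  expect_error(climate_spec(precip_factor = 0), "precip_factor")
  expect_error(climate_spec(anomaly_autocorr = 1), "anomaly_autocorr")
  expect_error(climate_spec(rh_mean = NaN), "rh_mean")
  # stationary frequency unreachable given the persistence
  expect_error(climate_spec(wet_day_prob = 0.9, wet_persistence = 0.1),
               "wet_day_prob")
  expect_error(generate_weather(climate_spec(), 0), "n_years")
})

test_that("weather CSV round-trips with the latitude header", {
  w <- generate_weather(climate_spec(seed = 6, latitude = 52), 1)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_weather_csv(w, path)
  w2 <- read_weather_csv(path)
  expect_equal(attr(w2, "latitude"), 52)
  expect_equal(w2$tav, w$tav, tolerance = 1e-12)
  expect_equal(w2$date, w$date)
})
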