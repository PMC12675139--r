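test_that("GDD follows the capped base-temperature formula", {
  expect_equal(compute_gdd(20), 12)
  expect_equal(compute_gdd(8), 0)
  expect_equal(compute_gdd(-5), 0)
  # capping at the upper threshold: a 35-degree day counts like a 30-degree day
  expect_equal(compute_gdd(35), 22)
  expect_equal(compute_gdd(35), compute_gdd(30))
  expect_error(compute_gdd(20, tbase = 30, tupper = 8), "tbase")
  # non-decreasing in tav, flat outside the active range
  tavs <- seq(-10, 45, by = 0.5)
  g <- compute_gdd(tavs)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g[tavs <= 8] == 0))
  expect_true(all(g[tavs >= 30] == 22))
  expect_true(all(g <= 30 - 8))
})

test_that("ETo vanishes when energy and aerodynamic forcing vanish", {
  w <- const_weather(tav = 15, precip = 0, rh = 100, wind10 = 0, srad = 0,
                     diurnal = 0)
  expect_equal(compute_eto(w), rep(0, nrow(w)))
})

test_that("ETo matches an independently coded FAO-56 oracle on a mid-summer day", {
  # warm clear day: tmax 30, tmin 18, RH giving ea near 2.1 kPa, strong
  # radiation, moderate wind, sea level
  w <- const_weather(tav = 24, rh = 71, wind10 = 2.7, srad = 22,
                     diurnal = 12, latitude = 45)
  day <- which(format(w$date, "%m-%d") == "07-15")
  got <- compute_eto(w, latitude = 45, elevation = 0)[day]
  want <- eto_fao56_oracle(tmin = 18, tmax = 30, rh = 71, wind10 = 2.7,
                           srad = 22, doy = 196, lat = 45, elev = 0)
  expect_lt(abs(got - want), 0.05)
  expect_gt(got, 3)  # a summer day like this evaporates several mm
})

test_that("ETo agrees with the FAO-56 oracle within 0.05 mm/day on 1000 random days", {
  set.seed(101)
  n <- 1000
  tmin <- runif(n, -5, 22)
  tmax <- tmin + runif(n, 1, 15)
  rh <- runif(n, 20, 100)
  wind10 <- runif(n, 0, 10)
  doy <- sample(1:365, n, replace = TRUE)
  lat <- runif(n, 35, 60)
  elev <- runif(n, 0, 1500)
  srad <- runif(n, 0.1, 0.8) * pmax(extraterrestrial_radiation(40, doy), 1)
  for (i in seq_len(n)) {
    w <- data.frame(date = as.Date("2001-01-01") + doy[i] - 1,
                    tmin = tmin[i], tmax = tmax[i],
                    tav = (tmin[i] + tmax[i]) / 2,
                    precip = 0, rh = rh[i], wind10 = wind10[i],
                    srad = srad[i], co2 = 400)
    got <- compute_eto(w, latitude = lat[i], elevation = elev[i])
    want <- eto_fao56_oracle(tmin[i], tmax[i], rh[i], wind10[i], srad[i],
                             doy[i], lat[i], elev[i])
    expect_lt(abs(got - want), 0.05)
  }
})

test_that("ETo responds monotonically to wind and radiation", {
  w <- const_weather(tav = 22, rh = 30, wind10 = 2, srad = 18, diurnal = 10)
  w2 <- w; w2$wind10 <- 4
  # doubling wind in a dry atmosphere never decreases ETo
  expect_true(all(compute_eto(w2) >= compute_eto(w)))
  w3 <- w; w3$srad <- 24
  expect_true(all(compute_eto(w3) >= compute_eto(w)))
})

test_that("ETo rejects invalid inputs", {
  w <- const_weather()
  w$rh[5] <- 140
  expect_error(compute_eto(w), "rh")
  w2 <- const_weather()
  w2$tmax[3] <- NaN
  expect_error(compute_eto(w2), "tmax")
})

test_that("annual aggregates sum daily values per calendar year", {
  # constant 18 C: 10 GDD/day, 3650 over a non-leap year
  w <- derive_climate(const_weather(tav = 18, year = 2001))
  agg <- annual_aggregates(w)
  expect_equal(agg$annual_gdd, 3650)
  expect_equal(agg$annual_precip, sum(w$precip))
  expect_equal(agg$annual_eto, sum(w$eto))

  # concatenating years aggregates with no cross-year leakage
  w2 <- derive_climate(const_weather(tav = 12, year = 2002))
  both <- rbind(w, w2)
  attr(both, "latitude") <- 45
  agg_both <- annual_aggregates(both)
  expect_equal(agg_both$annual_gdd, c(3650, 365 * 4))
  expect_equal(agg_both[1, -1], agg[1, -1], ignore_attr = TRUE)

  # partial years are rejected
  expect_error(annual_aggregates(w[-1, ]), "whole calendar years")
})

test_that("a uniform +2 offset in the unclipped range adds exactly 730 GDD/year", {
  w18 <- derive_climate(const_weather(tav = 18, year = 2001))
  w20 <- derive_climate(const_weather(tav = 20, year = 2001))
  a18 <- annual_aggregates(w18)
  a20 <- annual_aggregates(w20)
  expect_equal(a20$annual_gdd - a18$annual_gdd, 730)
})

test_that("identical periods give zero relative change for all drivers", {
  w <- derive_climate(const_weather(tav = 15))
  agg <- annual_aggregates(w)
  ch <- climate_change_summary(agg, agg)
  expect_equal(ch$relative_change_pct, rep(0, 3))
  # and a known perturbation gives the exact percentage
  agg2 <- agg
  agg2$annual_gdd <- agg$annual_gdd * 1.18
  ch2 <- climate_change_summary(agg, agg2)
  expect_equal(ch2$relative_change_pct[ch2$variable == "annual_gdd"], 18)
})
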