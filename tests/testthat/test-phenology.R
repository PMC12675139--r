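test_that("sowing triggers on the first in-window 4-day warm run", {
  # warm from 1 January: the qualifying run must lie inside the window, so
  # the earliest sowing day is 4 March (1-3 March count toward persistence)
  w <- const_weather(tav = 14, diurnal = 10)  # tmin = 9 everywhere
  expect_equal(find_sowing_date(w), as.Date("2001-03-04"))

  # cold window: fall back to 29 April
  w2 <- const_weather(tav = 10, diurnal = 10)  # tmin = 5
  expect_equal(find_sowing_date(w2), as.Date("2001-04-29"))

  # a 3-day warm spell never satisfies 4-day persistence
  w3 <- const_weather(tav = 10, diurnal = 10)
  warm_days <- w3$date >= as.Date("2001-03-10") & w3$date <= as.Date("2001-03-12")
  w3$tmin[warm_days] <- 9
  w3$tav[warm_days] <- 14
  w3$tmax[warm_days] <- 19
  expect_equal(find_sowing_date(w3), as.Date("2001-04-29"))

  # threshold is strict: tmin exactly 8 does not qualify
  w4 <- const_weather(tav = 13, diurnal = 10)  # tmin = 8
  expect_equal(find_sowing_date(w4), as.Date("2001-04-29"))

  expect_error(find_sowing_date(w[100:200, ]), "window")
})

test_that("sowing never falls outside the window over generated years", {
  ws <- as.Date("2001-03-01"); we <- as.Date("2001-04-29")
  for (sd in 1:6) {
    spec <- climate_spec(seed = sd, annual_mean_temp = 4 + 2 * sd)
    w <- generate_weather(spec, 1)
    s <- find_sowing_date(w)
    expect_true(s >= ws && s <= we)
  }
})

test_that("sowing rule parameters validate", {
  expect_error(sowing_rule(persistence = 0), "persistence")
  expect_error(sowing_rule(window_start = "04-29", window_end = "03-01"),
               "window_start")
  expect_error(sowing_rule(window_start = "13-40"), "window_start")
})

test_that("stage schedule reaches maturity by closed-form division", {
  # constant 19 C gives 11 GDD/day; 1122/11 = 102 days after sowing
  w <- const_weather(tav = 19)
  sowing <- as.Date("2001-04-20")
  sched <- stage_schedule(w, sowing)
  expect_equal(attr(sched, "maturity_date"), sowing + 102)
  expect_equal(sched$cum_gdd[1], 11)  # accumulation starts the day after sowing
  cc <- cycle_complete(w, sowing)
  expect_true(cc$complete)
  # emergence: ceil(80/11) = 8 days; cycle length 102 - 8 = 94
  expect_equal(cc$emergence_date, sowing + 8)
  expect_equal(cc$cycle_length, 94L)
})

test_that("no heat accumulation means no maturity", {
  w <- const_weather(tav = 7)
  cc <- cycle_complete(w, as.Date("2001-04-20"))
  expect_false(cc$complete)
  expect_true(is.na(cc$cycle_length))
  expect_equal(cc$total_gdd, 0)
})

test_that("cycle completion is inclusive exactly at the GDD threshold", {
  sowing <- as.Date("2001-04-20")
  build <- function(total) {
    # 101 days at 11 GDD + one final day topping up to `total`, then cold
    w <- const_weather(tav = 0, diurnal = 0)
    i_sow <- match(sowing, w$date)
    w$tav[(i_sow + 1):(i_sow + 101)] <- 19
    w$tav[i_sow + 102] <- 8 + (total - 101 * 11)
    w$tmin <- w$tav - 1; w$tmax <- w$tav + 1
    w
  }
  expect_true(cycle_complete(build(1122.0), sowing)$complete)
  expect_false(cycle_complete(build(1121.9), sowing)$complete)
})

test_that("stage labels are monotone and warming shortens the cycle", {
  w <- derive_climate(generate_weather(climate_spec(seed = 12,
                                                    annual_mean_temp = 11), 1))
  sowing <- find_sowing_date(w)
  sched <- stage_schedule(w, sowing)
  expect_true(all(diff(as.integer(sched$stage)) >= 0))

  # +2 C with tav kept inside the unclipped range: maturity strictly
  # earlier and cycle no longer, at fixed sowing
  w0 <- const_weather(tav = 18)
  w2 <- const_weather(tav = 20)
  s <- as.Date("2001-04-25")
  c0 <- cycle_complete(w0, s)
  c2 <- cycle_complete(w2, s)
  expect_lt(as.numeric(attr(stage_schedule(w2, s), "maturity_date")),
            as.numeric(attr(stage_schedule(w0, s), "maturity_date")))
  expect_lte(c2$cycle_length, c0$cycle_length)
})

test_that("warming moves sowing earlier and shortens cycles on generated series", {
  for (sd in c(2, 5, 9)) {
    w0 <- generate_weather(climate_spec(seed = sd, annual_mean_temp = 9,
                                        delta_T = 0), 1)
    w2 <- generate_weather(climate_spec(seed = sd, annual_mean_temp = 9,
                                        delta_T = 2), 1)
    s0 <- find_sowing_date(w0)
    s2 <- find_sowing_date(w2)
    expect_lte(as.numeric(s2), as.numeric(s0))
    c0 <- cycle_complete(w0, s0)
    c2 <- cycle_complete(w2, s0)  # same sowing date, warmer series
    if (c0$complete && c2$complete) {
      expect_lte(c2$cycle_length, c0$cycle_length)
    }
  }
})

test_that("crop parameter invariants are enforced", {
  expect_error(crop_parameters(gdd_emergence = 700), "gdd_emergence")
  expect_error(crop_parameters(gdd_flowering = 1000), "gdd_flowering")
  expect_error(crop_parameters(ccx = 1.2), "ccx")
  expect_error(crop_parameters(hi0 = 0), "hi0")
  expect_error(crop_parameters(tbase = 31), "tbase")
})
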