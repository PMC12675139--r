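test_that("the seasonal water balance closes to within 0.01 mm", {
  fixtures <- list(
    list(w = nonlimiting_weather(1), soil = soil_profile()),
    list(w = drought_weather(), soil = drought_soil()),
    list(w = derive_climate(generate_weather(climate_spec(seed = 21), 1),
                            elevation = 100), soil = soil_profile()))
  mgmts <- list(management_config(30), management_config(0),
                management_config(0, "net-requirement"))
  for (fx in fixtures) {
    sowing <- find_sowing_date(fx$w)
    for (mgmt in mgmts) {
      res <- simulate_season(fx$w, soil = fx$soil, mgmt = mgmt,
                             sowing = sowing)
      expect_lt(abs(res$balance_residual), 0.01)
      expect_gte(res$transpiration_sum, 0)
      expect_gte(res$evaporation_sum, 0)
      expect_gte(res$irrigation_sum, 0)
      expect_lte(res$yield_dry, res$biomass + 1e-12)
    }
  }
})

test_that("no available water means no transpiration and no yield", {
  w <- drought_weather()
  w$precip[] <- 0
  soil <- soil_profile(initial_fraction_fc = 0)  # start at wilting point
  res <- simulate_season(w, soil = soil, mgmt = management_config(0),
                         sowing = as.Date("2001-04-20"))
  expect_equal(res$transpiration_sum, 0)
  expect_equal(res$yield_dry, 0)
  expect_equal(res$biomass, 0)
})

test_that("net-requirement irrigation keeps depletion at or under the trigger", {
  w <- drought_weather()
  w$precip[] <- 0
  res <- simulate_season(w, soil = drought_soil(),
                         mgmt = management_config(0, "net-requirement"),
                         sowing = as.Date("2001-04-20"))
  expect_lte(res$max_raw_depletion_fraction, 0.5 + 1e-9)
  expect_gt(res$irrigation_sum, 0)
})

test_that("elevated CO2 raises biomass when water and fertility are non-limiting", {
  w <- nonlimiting_weather(2)
  sowing <- find_sowing_date(w)
  run_at <- function(ppm) {
    w2 <- w
    w2$co2[] <- ppm
    simulate_season(w2, mgmt = management_config(0), sowing = sowing)
  }
  expect_gte(run_at(700)$biomass, run_at(360)$biomass)
})

test_that("the CO2 factor is normalized, bounded and monotone", {
  expect_equal(f_co2(369.41), 1)
  expect_gt(f_co2(550), 1.0)
  expect_lte(f_co2(550), 1.10)
  grid <- seq(300, 1000, by = 10)
  expect_true(all(diff(f_co2(grid)) > 0))
  expect_error(f_co2(-10), "co2")
})

test_that("fertility calibration recovers the target relative biomass", {
  # identity at 100%
  cal100 <- calibrate_fertility(target_brel = 100)
  expect_equal(cal100$f_ccx_fert, 1)
  expect_equal(cal100$f_cc_fert, 1)
  expect_equal(cal100$f_wp_fert, 1)

  for (target in c(70, 50)) {
    cal <- calibrate_fertility(target_brel = target)
    expect_lt(abs(cal$achieved_brel - target), 0.5)
    # and the ratio transfers to an independent non-limiting season
    w <- nonlimiting_weather(3)
    sowing <- find_sowing_date(w)
    stressed <- simulate_season(w, mgmt = management_config(100 - target),
                                sowing = sowing)
    unstressed <- simulate_season(w, mgmt = management_config(0),
                                  sowing = sowing)
    expect_lt(abs(stressed$biomass / unstressed$biomass - target / 100),
              0.005)
  }
})

test_that("state variables stay inside their physical bounds", {
  for (fx in list(list(w = drought_weather(), soil = drought_soil()),
                  list(w = nonlimiting_weather(4), soil = soil_profile()))) {
    sowing <- find_sowing_date(fx$w)
    res <- simulate_season(fx$w, soil = fx$soil,
                           mgmt = management_config(30), sowing = sowing,
                           diagnostics = TRUE)
    d <- res$diagnostics
    cal <- calibrate_fertility(target_brel = 70)
    expect_true(all(d$cc >= 0 & d$cc <= 0.96 * cal$f_ccx_fert + 1e-12))
    expect_true(all(d$hi >= 0 & d$hi <= 0.48 + 1e-12))
    expect_true(all(d$ks_sto >= 0 & d$ks_sto <= 1))
    expect_true(all(d$ks_exp >= 0 & d$ks_exp <= 1))
    expect_true(all(diff(d$biomass) >= 0))
  }
})

test_that("adding water never decreases yield", {
  w <- drought_weather()
  sowing <- find_sowing_date(w)
  for (stress in c(0, 30)) {
    mgmt <- management_config(stress)
    y0 <- simulate_season(w, soil = drought_soil(), mgmt = mgmt,
                          sowing = sowing)$yield_dry
    w_plus <- w
    w_plus$precip <- w_plus$precip + 1.5
    y1 <- simulate_season(w_plus, soil = drought_soil(), mgmt = mgmt,
                          sowing = sowing)$yield_dry
    expect_gte(y1, y0)
    # switching irrigation on never decreases yield either
    y_irr <- simulate_season(w, soil = drought_soil(),
                             mgmt = management_config(stress,
                                                      "net-requirement"),
                             sowing = sowing)$yield_dry
    expect_gte(y_irr, y0)
  }
})

test_that("the engine is deterministic and incomplete seasons yield zero", {
  w <- nonlimiting_weather(5)
  sowing <- find_sowing_date(w)
  r1 <- simulate_season(w, sowing = sowing)
  r2 <- simulate_season(w, sowing = sowing)
  expect_identical(r1, r2)

  cold <- derive_climate(const_weather(tav = 10))
  res <- simulate_season(cold, sowing = as.Date("2001-04-29"))
  expect_false(res$complete)
  expect_equal(res$yield_dry, 0)
  expect_true(is.na(res$cycle_length))
})

test_that("soil and management invariants are enforced", {
  expect_error(soil_profile(theta_fc = 0.5, theta_sat = 0.4), "theta")
  expect_error(soil_profile(theta_wp = 0.3, theta_fc = 0.2), "theta")
  expect_error(management_config(fertility_stress = 120), "fertility_stress")
  expect_error(management_config(irrigation = "flood"), "should be one of")
  expect_error(management_config(irrigation_trigger_fraction = 0),
               "irrigation_trigger_fraction")
})
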