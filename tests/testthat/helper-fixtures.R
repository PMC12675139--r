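# Shared fixtures, all built in code.

# Whole-year series with constant forcing (a single calendar year).
const_weather <- function(tav = 19, year = 2001, precip = 10, rh = 70,
                          wind10 = 2, srad = 20, co2 = 369.41,
                          diurnal = 10, latitude = 45) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  w <- data.frame(date = dates,
                  tmin = tav - diurnal / 2, tmax = tav + diurnal / 2,
                  tav = tav, precip = precip, rh = rh, wind10 = wind10,
                  srad = srad, co2 = co2)
  attr(w, "latitude") <- latitude
  w
}

# One generated season with daily precipitation forced to at least twice
# ETo, so no water stress can occur.
nonlimiting_weather <- function(seed = 1, annual_mean_temp = 10) {
  spec <- climate_spec(seed = seed, annual_mean_temp = annual_mean_temp)
  w <- derive_climate(generate_weather(spec, 1, 2001), elevation = 100)
  w$precip <- pmax(w$precip, 2 * w$eto + 1)
  w
}

# Deterministic drought season: wet winter fills the profile, then no rain
# from late March on; warm enough to complete the cycle, with evaporative
# demand declining into autumn.
drought_weather <- function(mean_t = 10, amp = 9, rh = 50, lat = 42) {
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  tav <- mean_t + amp * cos(2 * pi * (doy - 196) / 365.25)
  w <- data.frame(date = dates, tmin = tav - 5, tmax = tav + 5, tav = tav,
                  precip = ifelse(doy < 90, 4, 0), rh = rh, wind10 = 3,
                  srad = pmax(0, extraterrestrial_radiation(lat, doy) * 0.7),
                  co2 = 369.41)
  attr(w, "latitude") <- lat
  derive_climate(w)
}

drought_soil <- function() soil_profile(max_root_depth = 1.0,
                                        initial_fraction_fc = 1)
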