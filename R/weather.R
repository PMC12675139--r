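#' Climate specification for the synthetic weather generator
#'
#' Describes the statistical climate of one grid cell: a sinusoidal annual
#' temperature cycle with first-order autocorrelated day-to-day anomalies, a
#' two-state (wet/dry) Markov chain for precipitation occurrence with
#' positively skewed wet-day amounts, latitude-dependent shortwave radiation
#' tied to wet/dry state, and scenario knobs (uniform warming offset,
#' multiplicative precipitation scaling, a linear annual CO2 trajectory).
#'
#' @param latitude Degrees north; controls radiation and the timing of the
#'   seasonal temperature peak (mid-July for northern latitudes).
#' @param annual_mean_temp Annual mean air temperature, degrees C.
#' @param seasonal_amplitude Half-range of the seasonal cycle, degrees C.
#' @param diurnal_range Daily tmax - tmin, degrees C.
#' @param anomaly_sd Stationary standard deviation of the AR(1) temperature
#'   anomaly, degrees C.
#' @param anomaly_autocorr Lag-1 autocorrelation of the anomaly, in `[0, 1)`.
#' @param wet_day_prob Stationary probability of a wet day, in `[0, 1]`.
#' @param wet_persistence Probability that a wet day follows a wet day.
#' @param mean_wet_amount Mean precipitation on wet days, mm/day.
#' @param rh_mean Mean relative humidity, percent.
#' @param wind10_mean Mean 10-m wind speed, m/s.
#' @param co2_start Atmospheric CO2 in the first simulated year, ppm.
#' @param delta_T Uniform warming offset added to tmin/tmax/tav, degrees C.
#' @param precip_factor Multiplier applied to every wet-day amount.
#' @param co2_trend Linear CO2 trend, ppm/year.
#' @param seed Integer RNG seed; identical (spec, seed) pairs reproduce the
#'   series bit for bit.
#' @return An object of class `climate_spec`.
#' @export
climate_spec <- function(latitude = 48,
                         annual_mean_temp = 10,
                         seasonal_amplitude = 9,
                         diurnal_range = 9,
                         anomaly_sd = 3,
                         anomaly_autocorr = 0.7,
                         wet_day_prob = 0.35,
                         wet_persistence = 0.6,
                         mean_wet_amount = 5,
                         rh_mean = 75,
                         wind10_mean = 3.5,
                         co2_start = 354,
                         delta_T = 0,
                         precip_factor = 1,
                         co2_trend = 1.7,
                         seed = 1L) {
  assert_number(latitude, "latitude", -90, 90)
  assert_number(annual_mean_temp, "annual_mean_temp", -50, 50)
  assert_number(seasonal_amplitude, "seasonal_amplitude", 0, 40)
  assert_number(diurnal_range, "diurnal_range", 0, 40)
  assert_number(anomaly_sd, "anomaly_sd", 0, Inf)
  assert_number(anomaly_autocorr, "anomaly_autocorr", 0, 1, strict_upper = TRUE)
  assert_number(wet_day_prob, "wet_day_prob", 0, 1)
  assert_number(wet_persistence, "wet_persistence", 0, 1)
  assert_number(mean_wet_amount, "mean_wet_amount", 0, Inf)
  assert_number(rh_mean, "rh_mean", 0, 100)
  assert_number(wind10_mean, "wind10_mean", 0, Inf)
  assert_number(co2_start, "co2_start", 0, Inf, strict_lower = TRUE)
  assert_number(delta_T, "delta_T", -20, 20)
  assert_number(precip_factor, "precip_factor", 0, Inf, strict_lower = TRUE)
  assert_number(co2_trend, "co2_trend", -10, 50)
  assert_count(seed, "seed", lower = 0L)
  # Wet/dry chain must admit the requested stationary frequency:
  # p(dry -> wet) = pi (1 - p11) / (1 - pi) has to be a probability.
  if (wet_day_prob < 1) {
    p01 <- wet_day_prob * (1 - wet_persistence) / (1 - wet_day_prob)
    if (p01 > 1 + 1e-12) {
      stopf("'wet_day_prob' = %g is unreachable with 'wet_persistence' = %g (dry-to-wet probability %g > 1)",
            wet_day_prob, wet_persistence, p01)
    }
  }
  structure(list(latitude = latitude,
                 annual_mean_temp = annual_mean_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_range = diurnal_range,
                 anomaly_sd = anomaly_sd,
                 anomaly_autocorr = anomaly_autocorr,
                 wet_day_prob = wet_day_prob,
                 wet_persistence = wet_persistence,
                 mean_wet_amount = mean_wet_amount,
                 rh_mean = rh_mean,
                 wind10_mean = wind10_mean,
                 co2_start = co2_start,
                 delta_T = delta_T,
                 precip_factor = precip_factor,
                 co2_trend = co2_trend,
                 seed = as.integer(seed)),
            class = "climate_spec")
}

#' Generate a daily weather series for one grid cell
#'
#' Produces `n_years` whole calendar years (leap days included) of daily
#' forcing: tmin/tmax/tav (sinusoidal cycle plus AR(1) anomalies plus the
#' scenario warming offset), precipitation from a two-state wet/dry chain
#' with gamma-distributed wet amounts scaled by `precip_factor`, relative
#' humidity, 10-m wind, shortwave radiation (extraterrestrial radiation for
#' the latitude and day of year times a wet/dry clearness factor), and the
#' annual CO2 value repeated daily.
#'
#' @param spec A [climate_spec()].
#' @param n_years Number of whole calendar years (>= 1).
#' @param start_year First calendar year of the series.
#' @return A `data.frame` with columns `date, tmin, tmax, tav, precip, rh,
#'   wind10, srad, co2`, one row per day, with the cell latitude attached as
#'   attribute `"latitude"`. `tav = (tmin + tmax)/2` by construction.
#' @export
generate_weather <- function(spec, n_years, start_year = 2001L) {
  if (!inherits(spec, "climate_spec")) stopf("'spec' must be a climate_spec")
  n_years <- assert_count(n_years, "n_years")
  start_year <- assert_count(start_year, "start_year", lower = 1L)

  dates <- seq(as.Date(sprintf("%04d-01-01", start_year)),
               as.Date(sprintf("%04d-12-31", start_year + n_years - 1L)),
               by = "day")
  n <- length(dates)
  doy <- doy_of(dates)
  yr <- year_of(dates)

  with_seed(spec$seed, {
    # --- temperature: seasonal sinusoid + AR(1) anomaly --------------------
    peak_doy <- if (spec$latitude >= 0) 196 else 15  # mid-July / mid-January
    seasonal <- spec$annual_mean_temp +
      spec$seasonal_amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
    rho <- spec$anomaly_autocorr
    innov <- stats::rnorm(n, 0, spec$anomaly_sd * sqrt(1 - rho^2))
    a0 <- stats::rnorm(1, 0, spec$anomaly_sd)
    anom <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                     init = a0))
    tav <- seasonal + anom + spec$delta_T
    tmin <- tav - spec$diurnal_range / 2
    tmax <- tav + spec$diurnal_range / 2

    # --- precipitation: two-state chain + scaled gamma amounts -------------
    p11 <- spec$wet_persistence
    p01 <- if (spec$wet_day_prob >= 1) 1 else {
      min(1, spec$wet_day_prob * (1 - p11) / (1 - spec$wet_day_prob))
    }
    u <- stats::runif(n)
    wet <- logical(n)
    wet[1] <- u[1] < spec$wet_day_prob
    if (n > 1) {
      for (i in 2:n) wet[i] <- u[i] < (if (wet[i - 1]) p11 else p01)
    }
    # amounts drawn for every day so the occurrence chain and the amount
    # stream stay aligned; precip_factor scales amounts only (exact scaling
    # under a shared seed)
    amt <- stats::rgamma(n, shape = 0.75,
                         scale = spec$mean_wet_amount / 0.75)
    precip <- ifelse(wet, spec$precip_factor * amt, 0)

    # --- humidity, wind ----------------------------------------------------
    rh <- clamp(spec$rh_mean + stats::rnorm(n, 0, 6) + ifelse(wet, 6, -2),
                5, 100)
    wind10 <- spec$wind10_mean * stats::rgamma(n, shape = 4, rate = 4)

    # --- shortwave radiation: Ra times a wet/dry clearness factor ----------
    ra <- extraterrestrial_radiation(spec$latitude, doy)
    kt <- ifelse(wet, 0.25, 0.55) + 0.20 * stats::runif(n)
    srad <- pmax(0, ra * kt)

    co2 <- spec$co2_start + (yr - start_year) * spec$co2_trend

    out <- data.frame(date = dates, tmin = tmin, tmax = tmax, tav = tav,
                      precip = precip, rh = rh, wind10 = wind10,
                      srad = srad, co2 = co2)
    attr(out, "latitude") <- spec$latitude
    out
  })
}

# Deterministic per-member perturbation of a climate_spec: distinct seed plus
# mild shifts of anomaly_sd and wet_day_prob so ensemble members differ in
# both noise and climatology. Member 1 is the unperturbed spec.
member_spec <- function(spec, member, n_members) {
  member <- assert_count(member, "member")
  base_pert <- c(0, -0.08, 0.08, -0.04, 0.04, -0.06, 0.06, -0.02, 0.02)
  pert <- rep_len(base_pert, max(n_members, member))[member]
  s <- spec
  s$anomaly_sd <- spec$anomaly_sd * (1 + pert)
  s$wet_day_prob <- clamp(spec$wet_day_prob * (1 - pert), 0.01, 0.95)
  s$seed <- derive_seed(spec$seed, member)
  if (member == 1L) s$seed <- spec$seed
  # re-validate (chain reachability may change with wet_day_prob)
  do.call(climate_spec, s)
}

#' Generate a small multi-member weather ensemble
#'
#' Emulates a small climate-model ensemble: each member uses a distinct seed
#' and mild deterministic perturbations of `anomaly_sd` and `wet_day_prob`,
#' so members differ in both weather noise and climatology. Member order is
#' stable; member 1 is identical to [generate_weather()] with the same seed.
#'
#' @inheritParams generate_weather
#' @param n_members Number of ensemble members (>= 1).
#' @return A list of `n_members` daily weather data frames.
#' @export
generate_ensemble <- function(spec, n_members, n_years, start_year = 2001L) {
  if (!inherits(spec, "climate_spec")) stopf("'spec' must be a climate_spec")
  n_members <- assert_count(n_members, "n_members")
  lapply(seq_len(n_members), function(m) {
    generate_weather(member_spec(spec, m, n_members), n_years, start_year)
  })
}

#' Validate a daily weather series
#'
#' Checks the structural invariants of a daily forcing table: required
#' columns, `tmin <= tav <= tmax` on every day, non-negative precipitation,
#' wind and radiation, relative humidity in `[0, 100]`, positive CO2, and
#' contiguous whole calendar years.
#'
#' @param weather A daily weather `data.frame`.
#' @return The input, invisibly; errors name the violated field.
#' @export
validate_daily_weather <- function(weather) {
  req <- c("date", "tmin", "tmax", "tav", "precip", "rh", "wind10",
           "srad", "co2")
  missing_cols <- setdiff(req, names(weather))
  if (length(missing_cols)) {
    stopf("weather is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (!inherits(weather$date, "Date")) stopf("'date' must be a Date column")
  if (any(weather$tmin > weather$tav + 1e-9) ||
      any(weather$tav > weather$tmax + 1e-9)) {
    stopf("temperature ordering violated: need tmin <= tav <= tmax")
  }
  if (any(weather$precip < 0)) stopf("'precip' must be >= 0")
  if (any(weather$rh < 0 | weather$rh > 100)) stopf("'rh' must be in [0, 100]")
  if (any(weather$wind10 < 0)) stopf("'wind10' must be >= 0")
  if (any(weather$srad < 0)) stopf("'srad' must be >= 0")
  if (any(weather$co2 <= 0)) stopf("'co2' must be > 0")
  d <- weather$date
  full <- seq(d[1], d[length(d)], by = "day")
  if (length(full) != length(d) || any(full != d)) {
    stopf("'date' must be contiguous daily dates")
  }
  if (format(d[1], "%m-%d") != "01-01" ||
      format(d[length(d)], "%m-%d") != "12-31") {
    stopf("series must cover whole calendar years (1 Jan to 31 Dec)")
  }
  invisible(weather)
}

#' Read and write per-cell daily weather as CSV
#'
#' The CSV layout is one row per day with columns
#' `date, tmin, tmax, tav, precip, rh, wind10, srad, co2` (and, if present,
#' the derived `eto` and `gdd` columns). The cell latitude is carried in a
#' `# latitude: <value>` comment header line.
#'
#' @param weather A daily weather `data.frame`.
#' @param path File path.
#' @return `write_weather_csv()` returns `path` invisibly;
#'   `read_weather_csv()` returns the weather `data.frame` with the
#'   `"latitude"` attribute restored.
#' @export
write_weather_csv <- function(weather, path) {
  lat <- attr(weather, "latitude")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(lat)) writeLines(sprintf("# latitude: %.6f", lat), con)
  utils::write.csv(as.data.frame(weather), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  first <- readLines(path, n = 1L)
  lat <- NULL
  if (startsWith(first, "# latitude:")) {
    lat <- as.numeric(sub("# latitude:", "", first, fixed = TRUE))
  }
  out <- utils::read.csv(path, comment.char = "#")
  out$date <- as.Date(out$date)
  if (!is.null(lat)) attr(out, "latitude") <- lat
  validate_daily_weather(out)
  out
}
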