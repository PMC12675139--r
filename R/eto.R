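#' Extraterrestrial radiation for a latitude and day of year
#'
#' Daily top-of-atmosphere solar radiation from the standard solar-geometry
#' relations (inverse relative Earth-Sun distance, solar declination, sunset
#' hour angle), in MJ m-2 day-1. Vectorised over `doy`.
#'
#' @param latitude Degrees north.
#' @param doy Day of year (1-366).
#' @return Numeric vector, MJ m-2 day-1 (0 during polar night).
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  assert_number(latitude, "latitude", -90, 90)
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(clamp(-tan(phi) * tan(delta), -1, 1))
  ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  pmax(ra, 0)
}

#' FAO-56 Penman-Monteith daily reference evapotranspiration
#'
#' Daily grass-reference evapotranspiration from the FAO-56 combination
#' equation: saturation vapour pressure as the mean of values at tmin and
#' tmax; actual vapour pressure from mean relative humidity applied to that
#' mean; slope of the vapour-pressure curve at tav; psychrometric constant
#' from elevation-derived pressure; net radiation as net shortwave (albedo
#' 0.23) minus net longwave (bounded below at zero), with clear-sky
#' radiation from extraterrestrial radiation; soil heat flux zero at the
#' daily scale; 10-m wind converted to 2 m with the FAO-56 logarithmic
#' profile factor (about 0.748). The result is floored at 0 mm/day.
#'
#' @param weather Daily weather `data.frame` (see [generate_weather()]); may
#'   be a single row or a whole series.
#' @param latitude Degrees north; defaults to the series' `"latitude"`
#'   attribute.
#' @param elevation Station elevation, m above sea level (default 0).
#' @return Numeric vector of ETo, mm/day, one value per row.
#' @export
compute_eto <- function(weather, latitude = attr(weather, "latitude"),
                        elevation = 0) {
  if (is.null(latitude)) stopf("'latitude' is required (no attribute found)")
  assert_number(latitude, "latitude", -90, 90)
  assert_number(elevation, "elevation", -430, 9000)
  for (col in c("tmin", "tmax", "tav", "rh", "wind10", "srad")) {
    if (!all(is.finite(weather[[col]]))) stopf("non-finite values in '%s'", col)
  }
  if (any(weather$rh < 0 | weather$rh > 100)) stopf("'rh' must be in [0, 100]")

  tmin <- weather$tmin; tmax <- weather$tmax; tav <- weather$tav
  rs <- weather$srad
  doy <- doy_of(weather$date)

  es_at <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (es_at(tmin) + es_at(tmax)) / 2
  ea <- weather$rh / 100 * es
  slope <- 4098 * es_at(tav) / (tav + 237.3)^2
  pressure <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * pressure
  u2 <- weather$wind10 * 4.87 / log(67.8 * 10 - 5.42)

  ra <- extraterrestrial_radiation(latitude, doy)
  rso <- (0.75 + 2e-5 * elevation) * ra
  rns <- (1 - 0.23) * rs
  rel_sw <- ifelse(rso > 0, pmin(rs / rso, 1), 0)
  sigma <- 4.903e-9
  rnl <- pmax(0,
              sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
                (0.34 - 0.14 * sqrt(pmax(ea, 0))) *
                (1.35 * rel_sw - 0.35))
  rn <- rns - rnl

  num <- 0.408 * slope * rn +
    gamma * (900 / (tav + 273)) * u2 * (es - ea)
  den <- slope + gamma * (1 + 0.34 * u2)
  pmax(0, num / den)
}

#' Append derived climate drivers to a weather series
#'
#' Adds the two derived daily drivers the analysis uses: FAO-56 reference
#' evapotranspiration (`eto`, mm/day) and growing degree days (`gdd`,
#' degree C day).
#'
#' @inheritParams compute_eto
#' @param tbase,tupper GDD base and upper temperature thresholds, degrees C.
#' @return The weather `data.frame` with `eto` and `gdd` columns appended.
#' @export
derive_climate <- function(weather, latitude = attr(weather, "latitude"),
                           elevation = 0, tbase = 8, tupper = 30) {
  weather$eto <- compute_eto(weather, latitude, elevation)
  weather$gdd <- compute_gdd(weather$tav, tbase, tupper)
  weather
}
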