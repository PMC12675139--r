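# Independent line-by-line FAO-56 reference-ET implementation, written
# scalar and equation-by-equation from the published equation sheet, as the
# oracle for compute_eto(). Deliberately kept separate in style and
# structure from the package implementation.
eto_fao56_oracle <- function(tmin, tmax, rh, wind10, srad, doy, lat,
                             elev = 0) {
  # Eq. 11: saturation vapour pressure at temperature T [kPa]
  eo <- function(temp) 0.6108 * exp((17.27 * temp) / (temp + 237.3))
  tmean <- (tmin + tmax) / 2
  # Eq. 12: mean saturation vapour pressure
  es <- (eo(tmax) + eo(tmin)) / 2
  # Eq. 19 variant: actual vapour pressure from mean relative humidity
  ea <- (rh / 100) * es
  # Eq. 13: slope of the saturation vapour pressure curve at Tmean
  big_delta <- (4098 * (0.6108 * exp((17.27 * tmean) / (tmean + 237.3)))) /
    (tmean + 237.3)^2
  # Eq. 7: atmospheric pressure from elevation
  p_atm <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
  # Eq. 8: psychrometric constant
  gam <- 0.665e-3 * p_atm
  # Eq. 47: wind speed at 2 m from 10-m measurement
  u2 <- wind10 * (4.87 / log(67.8 * 10 - 5.42))
  # Eq. 23: inverse relative distance Earth-Sun
  d_r <- 1 + 0.033 * cos((2 * pi / 365) * doy)
  # Eq. 24: solar declination
  dec <- 0.409 * sin((2 * pi / 365) * doy - 1.39)
  # Eq. 25-26: sunset hour angle (argument clipped for polar cases)
  phi <- pi / 180 * lat
  xx <- -tan(phi) * tan(dec)
  if (xx > 1) xx <- 1
  if (xx < -1) xx <- -1
  omega_s <- acos(xx)
  # Eq. 21: extraterrestrial radiation
  gsc <- 0.0820
  r_a <- (24 * 60 / pi) * gsc * d_r *
    (omega_s * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(omega_s))
  if (r_a < 0) r_a <- 0
  # Eq. 37: clear-sky solar radiation
  r_so <- (0.75 + 2e-5 * elev) * r_a
  # Eq. 38: net shortwave radiation, albedo 0.23
  r_ns <- (1 - 0.23) * srad
  # Eq. 39: net longwave radiation (relative shortwave capped at 1;
  # bounded below at zero: no net longwave gain)
  ratio <- if (r_so > 0) min(srad / r_so, 1) else 0
  r_nl <- 4.903e-9 *
    (((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2) *
    (0.34 - 0.14 * sqrt(ea)) *
    (1.35 * ratio - 0.35)
  if (r_nl < 0) r_nl <- 0
  # Eq. 40: net radiation; soil heat flux G = 0 at daily time steps
  r_n <- r_ns - r_nl
  g_soil <- 0
  # Eq. 6: the FAO Penman-Monteith equation
  et0 <- (0.408 * big_delta * (r_n - g_soil) +
            gam * (900 / (tmean + 273)) * u2 * (es - ea)) /
    (big_delta + gam * (1 + 0.34 * u2))
  if (et0 < 0) et0 <- 0
  et0
}
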