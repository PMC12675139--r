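#' Soil hydraulic profile for the root-zone bucket
#'
#' Single-layer root-zone bucket hydraulics: volumetric water contents at
#' saturation, field capacity and wilting point, a maximum effective rooting
#' depth, and the initial fill of the plant-available range.
#'
#' @param theta_sat,theta_fc,theta_wp Volumetric water content (m3/m3) at
#'   saturation, field capacity and wilting point; must satisfy
#'   `0 < theta_wp < theta_fc < theta_sat < 1`.
#' @param max_root_depth Maximum rooting depth the profile allows, m.
#' @param initial_fraction_fc Fraction of the plant-available range
#'   (field capacity minus wilting point) filled at simulation start:
#'   1 = field capacity, 0 = wilting point.
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(theta_sat = 0.46, theta_fc = 0.29, theta_wp = 0.13,
                         max_root_depth = 1.5, initial_fraction_fc = 1) {
  assert_number(theta_sat, "theta_sat", 0, 1, TRUE, TRUE)
  assert_number(theta_fc, "theta_fc", 0, 1, TRUE, TRUE)
  assert_number(theta_wp, "theta_wp", 0, 1, TRUE, TRUE)
  if (!(theta_wp < theta_fc && theta_fc < theta_sat)) {
    stopf("need 0 < theta_wp < theta_fc < theta_sat < 1")
  }
  assert_number(max_root_depth, "max_root_depth", 0, Inf, strict_lower = TRUE)
  assert_number(initial_fraction_fc, "initial_fraction_fc", 0, 1)
  structure(list(theta_sat = theta_sat, theta_fc = theta_fc,
                 theta_wp = theta_wp, max_root_depth = max_root_depth,
                 initial_fraction_fc = initial_fraction_fc),
            class = "soil_profile")
}

#' Management regime configuration
#'
#' Defines one of the three management regimes: the bulk soil-fertility
#' stress (percent; relative biomass production Brel = 100 - stress) and the
#' irrigation mode. `"net-requirement"` irrigation applies, at the end of
#' any day on which root-zone depletion would exceed
#' `irrigation_trigger_fraction` of the readily available water (RAW),
#' exactly the depth restoring depletion to that threshold (net irrigation,
#' no application losses).
#'
#' @param fertility_stress Percent in `[0, 100]` (default 30, the actual-yield
#'   regime).
#' @param irrigation `"off"` (rainfed) or `"net-requirement"`.
#' @param irrigation_trigger_fraction Fraction of RAW, in (0, 1] (default 0.5).
#' @return An object of class `management_config`.
#' @export
management_config <- function(fertility_stress = 30,
                              irrigation = c("off", "net-requirement"),
                              irrigation_trigger_fraction = 0.5) {
  assert_number(fertility_stress, "fertility_stress", 0, 100)
  irrigation <- match.arg(irrigation)
  assert_number(irrigation_trigger_fraction, "irrigation_trigger_fraction",
                0, 1, strict_lower = TRUE)
  structure(list(fertility_stress = fertility_stress,
                 irrigation = irrigation,
                 irrigation_trigger_fraction = irrigation_trigger_fraction),
            class = "management_config")
}

#' CO2 fertilization factor for a C4 crop
#'
#' Continuous, non-decreasing, saturating response normalized to 1 at the
#' reference concentration of 369.41 ppm:
#' `f = 1 + f_max * d / (|d| + k_half)` with `d = co2 - co2_ref`. The muted
#' asymptote (`1 + f_max`) reflects the weak CO2 response of the C4
#' photosynthetic pathway.
#'
#' @param co2 Atmospheric CO2 concentration, ppm (> 0); vectorised.
#' @param co2_ref Reference concentration, ppm.
#' @param f_max Saturating gain above the reference, unitless.
#' @param k_half Half-saturation scale, ppm.
#' @return Numeric factor(s), in `(1 - f_max, 1 + f_max)`.
#' @export
f_co2 <- function(co2, co2_ref = 369.41, f_max = 0.10, k_half = 200) {
  if (any(!is.finite(co2)) || any(co2 <= 0)) stopf("'co2' must be > 0")
  d <- co2 - co2_ref
  1 + f_max * d / (abs(d) + k_half)
}

# Map a scalar stress intensity s in [0, 1] to the three fertility factors.
# Canopy-dominant split: stress scales the whole canopy curve (both the
# maximum cover and the initial cover at emergence, so the logistic is the
# unstressed curve scaled pointwise) plus a milder normalized-water-
# productivity penalty. The pointwise canopy scaling makes the calibrated
# stressed/unstressed biomass ratio independent of the weather trajectory
# under non-limiting water, while still giving the stressed crop a smaller
# transpiring canopy (which is what makes Yw < Ya reachable under drought).
# The growth-rate factor f_cc_fert is kept in the factor set at weight 0.
fertility_factors <- function(s, weights = c(ccx = 0.70, cgc = 0.00, wp = 0.30)) {
  list(f_ccx_fert = 1 - weights[["ccx"]] * s,
       f_cc_fert = 1 - weights[["cgc"]] * s,
       f_wp_fert = 1 - weights[["wp"]] * s,
       stress_intensity = s)
}

# Deterministic reference forcing for the fertility calibration: a warm,
# radiation-rich season with daily rain far above ETo (no water stress).
reference_weather <- function(co2 = 369.41) {
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  n <- length(dates)
  doy <- doy_of(dates)
  tav <- 11 + 10 * cos(2 * pi * (doy - 196) / 365.25)
  out <- data.frame(date = dates,
                    tmin = tav - 5, tmax = tav + 5, tav = tav,
                    precip = 15, rh = 70, wind10 = 2,
                    srad = pmax(0, extraterrestrial_radiation(45, doy) * 0.65),
                    co2 = co2)
  attr(out, "latitude") <- 45
  derive_climate(out)
}

.fert_cache <- new.env(parent = emptyenv())

#' Calibrate fertility-stress factors to a target relative biomass
#'
#' One-dimensional search over a shared stress intensity mapped to the three
#' fertility factors (maximum canopy cover, canopy growth rate, normalized
#' water productivity) such that a reference season without water stress
#' reproduces an end-of-season biomass ratio (stressed over unstressed) of
#' `target_brel` percent, within 0.5 percentage points. Deterministic given
#' its inputs; results are memoised per (crop, soil, target).
#'
#' @param crop A [crop_parameters()].
#' @param soil A [soil_profile()].
#' @param target_brel Target relative biomass production, percent in
#'   (0, 100].
#' @return A list with the three factors (`f_ccx_fert`, `f_cc_fert`,
#'   `f_wp_fert`), the `stress_intensity` found, and the `achieved_brel` on
#'   the reference season.
#' @export
calibrate_fertility <- function(crop = crop_parameters(),
                                soil = soil_profile(),
                                target_brel = 70) {
  assert_number(target_brel, "target_brel", 0, 100, strict_lower = TRUE)
  key <- paste(collapse = "|",
               c(format(unlist(crop), digits = 12),
                 format(unlist(soil), digits = 12),
                 format(target_brel, digits = 12)))
  if (!is.null(.fert_cache[[key]])) return(.fert_cache[[key]])

  if (target_brel == 100) {
    out <- c(fertility_factors(0), list(achieved_brel = 100))
    .fert_cache[[key]] <- out
    return(out)
  }

  wx <- reference_weather()
  sowing <- as.Date("2001-04-20")
  mgmt0 <- management_config(fertility_stress = 0)
  soil_full <- soil
  soil_full$initial_fraction_fc <- 1
  biomass_at <- function(s) {
    res <- simulate_season_impl(wx, crop, soil_full, mgmt0, sowing,
                                fert = fertility_factors(s))
    res$biomass
  }
  b0 <- biomass_at(0)
  ratio_at <- function(s) biomass_at(s) / b0
  target <- target_brel / 100
  r1 <- ratio_at(1)
  if (r1 > target) {
    stopf("target Brel %.1f%% unattainable: reachable ratio interval is [%.1f%%, 100%%]",
          target_brel, 100 * r1)
  }
  root <- stats::uniroot(function(s) ratio_at(s) - target,
                         interval = c(0, 1), tol = 1e-7)
  out <- c(fertility_factors(root$root),
           list(achieved_brel = 100 * ratio_at(root$root)))
  .fert_cache[[key]] <- out
  out
}

# Resolve the fertility factors for a management config (memoised).
resolve_fertility <- function(crop, soil, mgmt) {
  if (mgmt$fertility_stress <= 0) return(fertility_factors(0))
  calibrate_fertility(crop, soil, 100 - mgmt$fertility_stress)
}

#' Simulate one growing season for one cell-year
#'
#' Daily-timestep water-driven growth simulation from sowing until maturity
#' or 31 December. Each day: (1) the root zone deepens from its initial
#' depth toward the maximum proportionally to cumulative GDD up to the
#' maximum-canopy threshold (water entering the zone with deepening is
#' tracked explicitly); (2) rain and irrigation enter the bucket, overflow
#' above saturation and half of any excess above field capacity leave as
#' runoff/drainage; (3) stress coefficients fall linearly from 1 to 0
#' between the readily-available-water threshold and total available water;
#' (4) canopy cover grows logistically per GDD (scaled by expansion stress
#' and fertility) toward its fertility-adjusted maximum and declines
#' exponentially after senescence; (5) crop transpiration is
#' `Ks_sto * kc_tr_x * CC * ETo` and soil evaporation
#' `ke_x * (1 - CC) * ETo` with a two-stage drying reduction, both limited
#' by water above wilting point; (6) biomass accumulates as
#' `wp_star * f_co2 * f_wp_fert * Tr/ETo`; (7) the harvest index builds
#' linearly in GDD from flowering to maturity up to its reference value,
#' each increment scaled by the stomatal stress coefficient (water stress
#' during yield formation reduces grain set);
#' (8) net-requirement irrigation tops depletion back up to the trigger
#' threshold at end of day. Seasons that do not accumulate the full cycle
#' GDD by 31 December are incomplete and yield zero.
#'
#' @param weather Daily weather for the sowing year with derived `eto` (see
#'   [derive_climate()]); must run to 31 December.
#' @param crop A [crop_parameters()].
#' @param soil A [soil_profile()].
#' @param mgmt A [management_config()].
#' @param sowing Sowing `Date` (from [find_sowing_date()]).
#' @param diagnostics If `TRUE`, attach a per-day diagnostic `data.frame`
#'   (canopy cover, store, depletion, fluxes, biomass, harvest index).
#' @return An object of class `season_result`: sowing/maturity dates,
#'   `complete` flag, `cycle_length` (emergence to maturity, days), dry
#'   grain `yield_dry` and `biomass` (ton/ha), seasonal `etc_sum`,
#'   `transpiration_sum`, `evaporation_sum` and `irrigation_sum` (mm),
#'   `max_raw_depletion_fraction`, and the water-balance terms with their
#'   closure `balance_residual` (mm).
#' @export
simulate_season <- function(weather, crop = crop_parameters(),
                            soil = soil_profile(),
                            mgmt = management_config(),
                            sowing, diagnostics = FALSE) {
  if (!inherits(crop, "crop_parameters")) stopf("'crop' must be crop_parameters")
  if (!inherits(soil, "soil_profile")) stopf("'soil' must be soil_profile")
  if (!inherits(mgmt, "management_config")) {
    stopf("'mgmt' must be management_config")
  }
  if (is.null(weather$eto)) {
    stopf("weather must carry an 'eto' column; run derive_climate() first")
  }
  fert <- resolve_fertility(crop, soil, mgmt)
  simulate_season_impl(weather, crop, soil, mgmt, sowing, fert,
                       diagnostics = diagnostics)
}

simulate_season_impl <- function(weather, crop, soil, mgmt, sowing, fert,
                                 diagnostics = FALSE) {
  sowing <- as.Date(sowing)
  i_sow <- match(sowing, weather$date)
  if (is.na(i_sow)) stopf("sowing date is not in the weather series")
  yr <- year_of(sowing)
  i_end <- match(as.Date(sprintf("%04d-12-31", yr)), weather$date)
  if (is.na(i_end)) stopf("weather series must run to 31 December of the sowing year")
  if (i_sow >= i_end) stopf("no days remain after sowing")

  tavv <- weather$tav
  prcv <- weather$precip
  etov <- weather$eto
  co2v <- weather$co2
  datev <- weather$date

  f_ccx <- fert$f_ccx_fert
  f_cc <- fert$f_cc_fert
  f_wp <- fert$f_wp_fert
  ccx_adj <- crop$ccx * f_ccx

  irrigate <- mgmt$irrigation == "net-requirement"
  trig <- mgmt$irrigation_trigger_fraction

  z0 <- crop$min_root_depth
  zmax <- min(crop$max_root_depth, soil$max_root_depth)
  theta_fc <- soil$theta_fc
  theta_wp <- soil$theta_wp
  theta_sat <- soil$theta_sat
  theta_init <- theta_wp + soil$initial_fraction_fc * (theta_fc - theta_wp)

  # two-stage soil-evaporation bookkeeping on a 0.10 m surface layer
  tew <- (theta_fc - 0.5 * theta_wp) * 100
  rew <- min(9, tew / 2)

  z <- z0
  theta <- theta_init
  cc <- 0
  emerged <- FALSE
  matured <- FALSE
  biomass <- 0
  cum <- 0
  de <- 0
  hi <- 0

  precip_sum <- 0; irr_sum <- 0; drain_sum <- 0; deepening_sum <- 0
  tr_sum <- 0; ev_sum <- 0; etc_sum <- 0; tr_season <- 0
  max_depl <- 0
  emergence_date <- as.Date(NA)
  maturity_date <- as.Date(NA)
  s_init <- theta * z * 1000

  days <- (i_sow + 1L):i_end
  if (diagnostics) {
    diag <- vector("list", length(days))
  }

  tb <- crop$tbase; tu <- crop$tupper
  step <- 0L
  for (i in days) {
    step <- step + 1L
    tav_i <- tavv[i]
    gdd_i <- tav_i
    if (gdd_i > tu) gdd_i <- tu
    gdd_i <- gdd_i - tb
    if (gdd_i < 0) gdd_i <- 0
    cum_prev <- cum
    cum <- cum + gdd_i

    # (1) root deepening; incoming soil water joins the bucket
    frac <- cum / crop$gdd_max_canopy
    if (frac > 1) frac <- 1
    znew <- z0 + (zmax - z0) * frac
    if (znew > z) {
      influx <- theta_init * (znew - z) * 1000
      theta <- (theta * z + theta_init * (znew - z)) / znew
      deepening_sum <- deepening_sum + influx
      z <- znew
    }

    # (2) water input and drainage
    p_i <- prcv[i]
    precip_sum <- precip_sum + p_i
    s <- theta * z * 1000 + p_i
    s_sat <- theta_sat * z * 1000
    s_fc <- theta_fc * z * 1000
    drain <- 0
    if (s > s_sat) {
      drain <- s - s_sat
      s <- s_sat
    }
    if (s > s_fc) {
      d2 <- 0.5 * (s - s_fc)
      drain <- drain + d2
      s <- s - d2
    }
    drain_sum <- drain_sum + drain
    theta <- s / (z * 1000)
    de <- de - p_i
    if (de < 0) de <- 0

    # (3) depletion and stress coefficients
    taw <- (theta_fc - theta_wp) * z * 1000
    dr <- s_fc - s
    if (dr < 0) dr <- 0
    raw_sto <- crop$p_upper * taw
    raw_exp <- crop$p_lower * taw
    ks_sto <- if (dr <= raw_sto) 1 else max(0, (taw - dr) / (taw - raw_sto))
    ks_exp <- if (dr <= raw_exp) 1 else max(0, (taw - dr) / (taw - raw_exp))

    # (4) canopy cover dynamics (per GDD)
    if (!emerged && cum >= crop$gdd_emergence) {
      emerged <- TRUE
      emergence_date <- datev[i]
      cc <- crop$cc0 * f_ccx  # initial cover scales with canopy fertility
    } else if (emerged) {
      if (cum < crop$gdd_senescence) {
        cc <- cc + crop$cgc * f_cc * ks_exp * gdd_i * cc * (1 - cc / ccx_adj)
      } else {
        cc <- cc * exp(-crop$cdc * gdd_i)
      }
      if (cc < 0) cc <- 0
      if (cc > ccx_adj) cc <- ccx_adj
    }

    # (5) transpiration and soil evaporation
    eto_i <- etov[i]
    tr_pot <- ks_sto * crop$kc_tr_x * cc * eto_i
    kr <- if (de <= rew) 1 else max(0, (tew - de) / (tew - rew))
    e_pot <- crop$ke_x * (1 - cc) * eto_i * kr
    e_cap <- tew - de
    if (e_cap < 0) e_cap <- 0
    if (e_pot > e_cap) e_pot <- e_cap
    avail <- (theta - theta_wp) * z * 1000
    if (avail < 0) avail <- 0
    tot <- tr_pot + e_pot
    if (tot > avail && tot > 0) {
      f <- avail / tot
      tr <- tr_pot * f
      ev <- e_pot * f
    } else {
      tr <- tr_pot
      ev <- e_pot
    }
    theta <- theta - (tr + ev) / (z * 1000)
    de <- de + ev
    tr_sum <- tr_sum + tr
    ev_sum <- ev_sum + ev
    if (emerged) {
      etc_sum <- etc_sum + tr + ev
      tr_season <- tr_season + tr
    }

    # (6) biomass accumulation
    if (emerged && eto_i > 0) {
      biomass <- biomass + crop$wp_star * f_co2(co2v[i]) * f_wp * (tr / eto_i)
    }

    # (7) harvest index build-up: linear in GDD from flowering to maturity,
    # modulated by stomatal stress (water stress during yield formation
    # reduces grain set; without water the index stalls)
    if (cum > crop$gdd_flowering) {
      g_lo <- if (cum_prev > crop$gdd_flowering) cum_prev else
        crop$gdd_flowering
      g_hi <- if (cum < crop$gdd_maturity) cum else crop$gdd_maturity
      if (g_hi > g_lo) {
        hi <- hi + crop$hi0 * ks_sto * (g_hi - g_lo) /
          (crop$gdd_maturity - crop$gdd_flowering)
        if (hi > crop$hi0) hi <- crop$hi0
      }
    }

    # (8) net-requirement irrigation: top depletion back to the trigger
    s <- theta * z * 1000
    dr_end <- theta_fc * z * 1000 - s
    if (dr_end < 0) dr_end <- 0
    if (irrigate && dr_end > trig * raw_sto) {
      irr <- dr_end - trig * raw_sto
      theta <- theta + irr / (z * 1000)
      irr_sum <- irr_sum + irr
      dr_end <- trig * raw_sto
      de <- de - irr
      if (de < 0) de <- 0
    }
    depl <- if (raw_sto > 0) dr_end / raw_sto else 0
    if (depl > max_depl) max_depl <- depl

    if (diagnostics) {
      diag[[step]] <- c(cc = cc, store = theta * z * 1000, dr = dr_end,
                        tr = tr, ev = ev, biomass = biomass, hi = hi,
                        ks_sto = ks_sto, ks_exp = ks_exp, root_depth = z)
    }

    if (cum >= crop$gdd_maturity) {
      matured <- TRUE
      maturity_date <- datev[i]
      break
    }
  }

  s_end <- theta * z * 1000
  residual <- (precip_sum + irr_sum + deepening_sum + s_init - s_end) -
    (tr_sum + ev_sum + drain_sum)

  biomass_tonha <- biomass / 100  # g/m2 -> ton/ha
  yield <- if (matured) biomass_tonha * hi else 0

  out <- list(sowing_date = sowing,
              maturity_date = maturity_date,
              emergence_date = emergence_date,
              complete = matured,
              cycle_length = if (matured && !is.na(emergence_date)) {
                as.integer(maturity_date - emergence_date)
              } else NA_integer_,
              yield_dry = yield,
              biomass = biomass_tonha,
              harvest_index = if (matured) hi else 0,
              etc_sum = etc_sum,
              transpiration_sum = tr_season,
              evaporation_sum = ev_sum,
              irrigation_sum = irr_sum,
              precip_sum = precip_sum,
              drainage_sum = drain_sum,
              deepening_influx = deepening_sum,
              storage_initial = s_init,
              storage_final = s_end,
              balance_residual = residual,
              max_raw_depletion_fraction = max_depl,
              fertility = fert[c("f_ccx_fert", "f_cc_fert", "f_wp_fert")])
  if (diagnostics) {
    out$diagnostics <- as.data.frame(do.call(rbind, diag[seq_len(step)]))
    out$diagnostics$date <- datev[days[seq_len(step)]]
  }
  class(out) <- "season_result"
  out
}

#' @export
print.season_result <- function(x, ...) {
  cat("Season result\n")
  cat(sprintf("  sowing: %s  maturity: %s  complete: %s\n",
              format(x$sowing_date), format(x$maturity_date), x$complete))
  cat(sprintf("  yield: %.2f ton/ha  biomass: %.2f ton/ha  cycle: %s days\n",
              x$yield_dry, x$biomass,
              ifelse(is.na(x$cycle_length), "NA", x$cycle_length)))
  cat(sprintf("  ETc: %.1f mm  Tr: %.1f mm  irrigation: %.1f mm\n",
              x$etc_sum, x$transpiration_sum, x$irrigation_sum))
  invisible(x)
}

#' Per-season diagnostic CSV
#'
#' Writes the daily diagnostic table of a season simulated with
#' `diagnostics = TRUE` (canopy cover, root-zone store and depletion, daily
#' transpiration/evaporation, biomass, harvest index, stress coefficients,
#' root depth).
#'
#' @param result A `season_result` carrying diagnostics.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_season_diagnostics <- function(result, path) {
  if (is.null(result$diagnostics)) {
    stopf("season was simulated without diagnostics = TRUE")
  }
  utils::write.csv(result$diagnostics, path, row.names = FALSE)
  invisible(path)
}
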