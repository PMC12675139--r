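#' Parameters of the generic grain maize cultivar
#'
#' Phenology is expressed in cumulative growing degree days (GDD) counted
#' from the day after sowing; one cultivar is used everywhere, so warmer
#' conditions shorten the calendar-day cycle rather than changing the crop.
#' Growth/production coefficients follow the conventions of water-driven
#' crop models: canopy cover dynamics (`cc0`, `cgc`, `ccx`, `cdc`), a
#' transpiration crop coefficient at full canopy (`kc_tr_x`), normalized
#' water productivity (`wp_star`, biomass per unit of transpiration relative
#' to reference evapotranspiration), a reference harvest index (`hi0`), and
#' root-zone depletion fractions at which stomatal closure (`p_upper`) and
#' canopy expansion (`p_lower`) stress begin.
#'
#' @param tbase,tupper GDD temperature thresholds, degrees C (8 and 30).
#' @param gdd_emergence GDD from sowing to emergence (germination).
#' @param gdd_max_canopy GDD from sowing to maximum canopy cover.
#' @param gdd_flowering GDD from sowing to flowering (start of yield
#'   formation).
#' @param gdd_senescence GDD from sowing to the start of canopy decline.
#' @param gdd_maturity Total cycle GDD from sowing to maturity (1122).
#' @param kc_tr_x Transpiration coefficient at full canopy, unitless.
#' @param ccx Maximum canopy cover, fraction in (0, 1].
#' @param cc0 Initial canopy cover at emergence, fraction.
#' @param cgc Canopy growth coefficient, per GDD.
#' @param cdc Canopy decline coefficient, per GDD.
#' @param wp_star Normalized water productivity, g/m2.
#' @param hi0 Reference harvest index, fraction in (0, 1).
#' @param p_upper Depletion fraction of TAW at which stomatal stress starts.
#' @param p_lower Depletion fraction of TAW at which expansion stress starts.
#' @param max_root_depth Maximum effective rooting depth, m.
#' @param min_root_depth Rooting depth at sowing, m.
#' @param ke_x Maximum soil evaporation coefficient, unitless.
#' @return An object of class `crop_parameters`.
#' @export
crop_parameters <- function(tbase = 8, tupper = 30,
                            gdd_emergence = 80,
                            gdd_max_canopy = 673,
                            gdd_flowering = 620,
                            gdd_senescence = 898,
                            gdd_maturity = 1122,
                            kc_tr_x = 1.05,
                            ccx = 0.96,
                            cc0 = 0.0065,
                            cgc = 0.013,
                            cdc = 0.004,
                            wp_star = 33.7,
                            hi0 = 0.48,
                            p_upper = 0.5,
                            p_lower = 0.25,
                            max_root_depth = 1.5,
                            min_root_depth = 0.3,
                            ke_x = 1.10) {
  assert_number(tbase, "tbase", -50, 50)
  assert_number(tupper, "tupper", -50, 60)
  if (tbase >= tupper) stopf("'tbase' must be below 'tupper'")
  assert_number(gdd_emergence, "gdd_emergence", 0, Inf, strict_lower = TRUE)
  assert_number(gdd_max_canopy, "gdd_max_canopy", 0, Inf, strict_lower = TRUE)
  assert_number(gdd_flowering, "gdd_flowering", 0, Inf, strict_lower = TRUE)
  assert_number(gdd_senescence, "gdd_senescence", 0, Inf, strict_lower = TRUE)
  assert_number(gdd_maturity, "gdd_maturity", 0, Inf, strict_lower = TRUE)
  if (!(gdd_emergence < gdd_max_canopy && gdd_max_canopy <= gdd_senescence &&
        gdd_senescence < gdd_maturity)) {
    stopf("need gdd_emergence < gdd_max_canopy <= gdd_senescence < gdd_maturity")
  }
  if (gdd_flowering < gdd_emergence || gdd_flowering > gdd_senescence) {
    stopf("'gdd_flowering' must lie between gdd_emergence and gdd_senescence")
  }
  assert_number(kc_tr_x, "kc_tr_x", 0, Inf, strict_lower = TRUE)
  assert_number(ccx, "ccx", 0, 1, strict_lower = TRUE)
  assert_number(cc0, "cc0", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_number(cgc, "cgc", 0, Inf, strict_lower = TRUE)
  assert_number(cdc, "cdc", 0, Inf, strict_lower = TRUE)
  assert_number(wp_star, "wp_star", 0, Inf, strict_lower = TRUE)
  assert_number(hi0, "hi0", 0, 1, strict_lower = TRUE)
  assert_number(p_upper, "p_upper", 0, 1, strict_lower = TRUE)
  assert_number(p_lower, "p_lower", 0, 1, strict_lower = TRUE)
  assert_number(max_root_depth, "max_root_depth", 0, Inf, strict_lower = TRUE)
  assert_number(min_root_depth, "min_root_depth", 0, max_root_depth,
                strict_lower = TRUE)
  assert_number(ke_x, "ke_x", 0, Inf, strict_lower = TRUE)
  structure(list(tbase = tbase, tupper = tupper,
                 gdd_emergence = gdd_emergence,
                 gdd_max_canopy = gdd_max_canopy,
                 gdd_flowering = gdd_flowering,
                 gdd_senescence = gdd_senescence,
                 gdd_maturity = gdd_maturity,
                 kc_tr_x = kc_tr_x, ccx = ccx, cc0 = cc0,
                 cgc = cgc, cdc = cdc, wp_star = wp_star, hi0 = hi0,
                 p_upper = p_upper, p_lower = p_lower,
                 max_root_depth = max_root_depth,
                 min_root_depth = min_root_depth,
                 ke_x = ke_x),
            class = "crop_parameters")
}

#' Temperature-dependent sowing rule
#'
#' Sowing happens on the first day of the window on which the daily minimum
#' temperature has exceeded the threshold on `persistence` consecutive days,
#' that run lying entirely inside the window and ending on (and including)
#' the sowing day. If no day qualifies, sowing falls back to the last day of
#' the window.
#'
#' @param window_start,window_end Window bounds as `"MM-DD"` strings
#'   (defaults 1 March and 29 April).
#' @param tmin_threshold Minimum-temperature threshold, degrees C (8).
#' @param persistence Required run of qualifying days (4).
#' @return An object of class `sowing_rule`.
#' @export
sowing_rule <- function(window_start = "03-01", window_end = "04-29",
                        tmin_threshold = 8, persistence = 4L) {
  chk <- function(x, name) {
    if (!is.character(x) || length(x) != 1L ||
        is.na(as.Date(paste0("2001-", x), optional = TRUE))) {
      stopf("'%s' must be an 'MM-DD' string", name)
    }
  }
  chk(window_start, "window_start")
  chk(window_end, "window_end")
  if (as.Date(paste0("2001-", window_start)) >=
      as.Date(paste0("2001-", window_end))) {
    stopf("'window_start' must precede 'window_end'")
  }
  assert_number(tmin_threshold, "tmin_threshold", -50, 50)
  persistence <- assert_count(persistence, "persistence")
  structure(list(window_start = window_start, window_end = window_end,
                 tmin_threshold = tmin_threshold,
                 persistence = persistence),
            class = "sowing_rule")
}

#' Find the sowing date for one year
#'
#' Scans the sowing window for the first day `d` such that tmin exceeded the
#' threshold on each of the `persistence` consecutive days ending at `d`,
#' all inside the window. Returns the window end if the criterion is never
#' met, so sowing never falls outside the window.
#'
#' @param year_weather Daily weather covering at least 1 January through the
#'   window end of a single year.
#' @param rule A [sowing_rule()].
#' @return The sowing `Date`.
#' @export
find_sowing_date <- function(year_weather, rule = sowing_rule()) {
  if (!inherits(rule, "sowing_rule")) stopf("'rule' must be a sowing_rule")
  yr <- year_of(year_weather$date[1])
  ws <- as.Date(sprintf("%04d-%s", yr, rule$window_start))
  we <- as.Date(sprintf("%04d-%s", yr, rule$window_end))
  idx <- match(seq(ws, we, by = "day"), year_weather$date)
  if (anyNA(idx)) stopf("weather series does not cover the sowing window")
  tmin <- year_weather$tmin[idx]
  warm <- tmin > rule$tmin_threshold
  p <- rule$persistence
  n <- length(warm)
  if (n >= p) {
    for (d in p:n) {
      if (all(warm[(d - p + 1):d])) return(year_weather$date[idx[d]])
    }
  }
  we
}

#' Cumulative GDD schedule and stage labels from sowing
#'
#' Accumulates daily GDD starting the day after sowing and labels each day
#' by comparing cumulative GDD to the crop's stage thresholds:
#' `pre-emergence`, `vegetative`, `flowering`, `senescence`, `mature`.
#'
#' @param weather Daily weather for the sowing year (must contain the
#'   sowing date and run to 31 December).
#' @param sowing Sowing `Date`.
#' @param crop A [crop_parameters()].
#' @return A `data.frame` with columns `date, gdd, cum_gdd, stage` for the
#'   days after sowing, with attributes `maturity_date` and
#'   `emergence_date` (`NA` if not reached by 31 December).
#' @export
stage_schedule <- function(weather, sowing, crop = crop_parameters()) {
  if (!inherits(crop, "crop_parameters")) {
    stopf("'crop' must be crop_parameters")
  }
  i_sow <- match(as.Date(sowing), weather$date)
  if (is.na(i_sow)) stopf("sowing date is not in the weather series")
  yr <- year_of(as.Date(sowing))
  year_end <- as.Date(sprintf("%04d-12-31", yr))
  i_end <- match(year_end, weather$date)
  if (is.na(i_end)) stopf("weather series must run to 31 December of the sowing year")
  if (i_sow >= i_end) stopf("no days remain after sowing")

  idx <- (i_sow + 1L):i_end
  gdd <- compute_gdd(weather$tav[idx], crop$tbase, crop$tupper)
  cum <- cumsum(gdd)
  stage <- cut(cum,
               breaks = c(-Inf, crop$gdd_emergence, crop$gdd_flowering,
                          crop$gdd_senescence, crop$gdd_maturity, Inf),
               labels = c("pre-emergence", "vegetative", "flowering",
                          "senescence", "mature"),
               right = FALSE)
  # boundary inclusive: reaching a threshold exactly counts as attained
  stage[cum >= crop$gdd_maturity] <- "mature"
  out <- data.frame(date = weather$date[idx], gdd = gdd, cum_gdd = cum,
                    stage = stage)
  mat <- which(cum >= crop$gdd_maturity)[1]
  eme <- which(cum >= crop$gdd_emergence)[1]
  attr(out, "maturity_date") <- if (is.na(mat)) as.Date(NA) else out$date[mat]
  attr(out, "emergence_date") <- if (is.na(eme)) as.Date(NA) else out$date[eme]
  out
}

#' Cycle-completion test and cycle length
#'
#' A cell-year completes its cycle when cumulative GDD from sowing to 31
#' December reaches the total cycle requirement (comparison inclusive at the
#' threshold). The cycle length is counted in calendar days from emergence
#' (germination) to maturity; incomplete cycles report no length.
#'
#' @inheritParams stage_schedule
#' @return A list with elements `complete` (logical), `cycle_length` (days,
#'   `NA` if incomplete), `maturity_date`, `emergence_date`, and
#'   `total_gdd` accumulated by 31 December.
#' @export
cycle_complete <- function(weather, sowing, crop = crop_parameters()) {
  sched <- stage_schedule(weather, sowing, crop)
  total <- sched$cum_gdd[nrow(sched)]
  complete <- total >= crop$gdd_maturity
  mat <- attr(sched, "maturity_date")
  eme <- attr(sched, "emergence_date")
  list(complete = complete,
       cycle_length = if (complete && !is.na(eme)) {
         as.integer(mat - eme)
       } else NA_integer_,
       maturity_date = mat,
       emergence_date = eme,
       total_gdd = total)
}
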