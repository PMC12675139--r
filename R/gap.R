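#' Run the three management regimes for one cell-year
#'
#' Runs [simulate_season()] three times with identical weather and sowing
#' date, differing only in management: actual yield Ya (default 30%
#' fertility stress, rainfed), water-limited yield Yw (0% fertility stress,
#' rainfed), and potential yield Yp (0% fertility stress plus
#' net-requirement irrigation keeping root-zone depletion above the trigger
#' fraction of readily available water).
#'
#' @inheritParams simulate_season
#' @param fertility_stress Fertility stress of the Ya regime, percent.
#' @param irrigation_trigger_fraction Yp irrigation trigger, fraction of RAW.
#' @return A list of class `regime_triplet` with elements `ya`, `yw`, `yp`
#'   (dry yields, ton/ha), `etc_a`, `etc_w`, `etc_p` (seasonal ETc, mm), and
#'   the three full `season_result` objects under `seasons`.
#' @export
run_regimes <- function(weather, crop = crop_parameters(),
                        soil = soil_profile(), sowing,
                        fertility_stress = 30,
                        irrigation_trigger_fraction = 0.5) {
  mgmt_a <- management_config(fertility_stress = fertility_stress,
                              irrigation = "off")
  mgmt_w <- management_config(fertility_stress = 0, irrigation = "off")
  mgmt_p <- management_config(fertility_stress = 0,
                              irrigation = "net-requirement",
                              irrigation_trigger_fraction =
                                irrigation_trigger_fraction)
  sa <- simulate_season(weather, crop, soil, mgmt_a, sowing)
  sw <- simulate_season(weather, crop, soil, mgmt_w, sowing)
  sp <- simulate_season(weather, crop, soil, mgmt_p, sowing)
  structure(list(ya = sa$yield_dry, yw = sw$yield_dry, yp = sp$yield_dry,
                 etc_a = sa$etc_sum, etc_w = sw$etc_sum, etc_p = sp$etc_sum,
                 complete = sa$complete,
                 sowing_date = sa$sowing_date,
                 cycle_length = sa$cycle_length,
                 seasons = list(ya = sa, yw = sw, yp = sp)),
            class = "regime_triplet")
}

#' Water-limited and potential yield gaps
#'
#' `YGw = (1 - Ya/Yw) * 100` and `YGp = (1 - Ya/Yp) * 100`, computed on
#' multi-year mean yields. Negative YGw is a valid outcome (the unstressed
#' crop's larger canopy can deplete water sooner under drought and finish
#' below the fertility-stressed crop). Zero or non-positive denominators
#' give `NA` with a warning rather than a silent 0.
#'
#' @param mean_ya,mean_yw,mean_yp Mean yields, ton/ha (`mean_yp` optional).
#' @return A list with `ygw` and `ygp` in percent (`ygp` is `NA` when
#'   `mean_yp` is missing).
#' @export
yield_gaps <- function(mean_ya, mean_yw, mean_yp = NA_real_) {
  gap1 <- function(ya, yx, name) {
    if (is.na(yx)) return(NA_real_)
    if (!is.finite(yx) || yx <= 0) {
      warning(sprintf("%s undefined: non-positive denominator", name),
              call. = FALSE)
      return(NA_real_)
    }
    (1 - ya / yx) * 100
  }
  list(ygw = gap1(mean_ya, mean_yw, "YGw"),
       ygp = gap1(mean_ya, mean_yp, "YGp"))
}

#' Crop water productivity
#'
#' Yield per unit of seasonal crop evapotranspiration:
#' `WP = 100 * yield / ETc` in kg grain per m3 of water (1 ton/ha = 0.1
#' kg/m2 and 1 mm = 0.001 m3/m2, hence the factor 100).
#'
#' @param yield_dry Dry grain yield, ton/ha; vectorised.
#' @param etc_sum Seasonal crop evapotranspiration (germination to
#'   maturity), mm.
#' @return WP in kg/m3; `NA` with a warning where `etc_sum <= 0`.
#' @export
water_productivity <- function(yield_dry, etc_sum) {
  out <- ifelse(etc_sum > 0, 100 * yield_dry / etc_sum, NA_real_)
  if (any(!is.na(yield_dry) & (etc_sum <= 0))) {
    warning("water productivity undefined where etc_sum <= 0", call. = FALSE)
  }
  out
}

#' Spatial skill metrics against reference yields
#'
#' Pearson correlation, bias and root-mean-square difference between paired
#' reference and simulated yields. The bias convention is
#' `mean(reference - simulated)`: positive bias means the simulation
#' underestimates the reference.
#'
#' @param reference,simulated Paired numeric vectors (length >= 2).
#' @return A list with `pearson_r`, `bias` and `rmsd` (yield units).
#' @export
skill_metrics <- function(reference, simulated) {
  if (length(reference) != length(simulated)) {
    stopf("'reference' and 'simulated' must have equal length")
  }
  if (length(reference) < 2L) stopf("need at least 2 paired values")
  d <- reference - simulated
  list(pearson_r = stats::cor(reference, simulated),
       bias = mean(d),
       rmsd = sqrt(mean(d^2)))
}

#' Multi-year cell statistics from per-year regime results
#'
#' Aggregates a series of per-year [run_regimes()] triplets for one cell
#' into the statistics the analysis maps: mean and interannual SD of
#' Ya/Yw/Yp over complete years, yield gaps computed on the mean yields,
#' water productivity (by default the ratio of mean yield to mean seasonal
#' ETc; `wp_method = "per-year"` averages per-year WP instead), mean sowing
#' day of year and cycle length, the number of complete years, and the
#' number of crop failures (years with Ya below `failure_threshold`;
#' incomplete years yield 0 and therefore count as failures).
#'
#' @param triplets A list of `regime_triplet` objects (one per year).
#' @param failure_threshold Crop-failure yield threshold, ton/ha (4).
#' @param wp_method `"ratio"` (default) or `"per-year"`.
#' @return A one-row `data.frame` of cell statistics.
#' @export
cell_statistics <- function(triplets, failure_threshold = 4,
                            wp_method = c("ratio", "per-year")) {
  wp_method <- match.arg(wp_method)
  get <- function(f) vapply(triplets, `[[`, numeric(1), f)
  ya <- get("ya"); yw <- get("yw"); yp <- get("yp")
  etc_a <- get("etc_a"); etc_w <- get("etc_w"); etc_p <- get("etc_p")
  complete <- vapply(triplets, `[[`, logical(1), "complete")
  sow_doy <- vapply(triplets, function(t) doy_of(t$sowing_date), integer(1))
  cyc <- vapply(triplets, function(t) {
    if (is.na(t$cycle_length)) NA_real_ else as.numeric(t$cycle_length)
  }, numeric(1))

  n_complete <- sum(complete)
  cm <- complete  # incomplete years excluded from means, not zero-filled
  mean_or_na <- function(x) if (any(cm)) mean(x[cm]) else NA_real_
  sd_or_na <- function(x) if (sum(cm) > 1) stats::sd(x[cm]) else NA_real_

  mean_ya <- mean_or_na(ya); mean_yw <- mean_or_na(yw); mean_yp <- mean_or_na(yp)
  gaps <- if (!is.na(mean_ya)) yield_gaps(mean_ya, mean_yw, mean_yp) else
    list(ygw = NA_real_, ygp = NA_real_)

  wp_of <- function(y, etc) {
    if (!any(cm)) return(NA_real_)
    if (wp_method == "ratio") {
      me <- mean(etc[cm])
      if (me <= 0) NA_real_ else 100 * mean(y[cm]) / me
    } else {
      mean(water_productivity(y[cm], etc[cm]))
    }
  }

  data.frame(mean_ya = mean_ya, mean_yw = mean_yw, mean_yp = mean_yp,
             sd_ya = sd_or_na(ya), sd_yw = sd_or_na(yw), sd_yp = sd_or_na(yp),
             ygw = gaps$ygw, ygp = gaps$ygp,
             wpa = wp_of(ya, etc_a), wpw = wp_of(yw, etc_w),
             wpp = wp_of(yp, etc_p),
             mean_sowing_doy = mean(sow_doy),
             mean_cycle_length = if (any(cm)) mean(cyc[cm]) else NA_real_,
             n_complete_years = n_complete,
             n_failures = count_failures(ya, threshold = failure_threshold))
}
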