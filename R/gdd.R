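#' Growing degree days
#'
#' Daily heat accumulation `max(0, min(tav, tupper) - tbase)`: no
#' development below the base temperature, and temperatures above the upper
#' threshold are capped (excess heat does not accelerate development).
#'
#' @param tav Daily mean air temperature(s), degrees C; vectorised.
#' @param tbase Base temperature, degrees C (default 8).
#' @param tupper Upper temperature threshold, degrees C (default 30).
#' @return Numeric vector of GDD, degree C day, in `[0, tupper - tbase]`.
#' @export
compute_gdd <- function(tav, tbase = 8, tupper = 30) {
  assert_number(tbase, "tbase", -50, 50)
  assert_number(tupper, "tupper", -50, 60)
  if (tbase >= tupper) stopf("'tbase' (%g) must be below 'tupper' (%g)",
                             tbase, tupper)
  pmax(0, pmin(tav, tupper) - tbase)
}

#' Annual climate aggregates
#'
#' Per-calendar-year sums of precipitation, growing degree days and
#' reference evapotranspiration from a derived weather series (see
#' [derive_climate()]). The series must cover whole calendar years.
#'
#' @param weather Daily weather `data.frame` with `eto` and `gdd` columns.
#' @return A `data.frame` with one row per year and columns
#'   `year, annual_precip, annual_gdd, annual_eto`.
#' @export
annual_aggregates <- function(weather) {
  validate_daily_weather(weather)
  if (is.null(weather$eto) || is.null(weather$gdd)) {
    stopf("weather must carry 'eto' and 'gdd' columns; run derive_climate() first")
  }
  yr <- year_of(weather$date)
  agg <- function(x) tapply(x, yr, sum)
  out <- data.frame(year = as.integer(names(agg(weather$precip))),
                    annual_precip = as.numeric(agg(weather$precip)),
                    annual_gdd = as.numeric(agg(weather$gdd)),
                    annual_eto = as.numeric(agg(weather$eto)))
  rownames(out) <- NULL
  out
}

#' Multi-year means and relative change between two periods
#'
#' Compares two annual-aggregate tables (baseline and future periods) on the
#' climate drivers: multi-year means of annual precipitation, GDD and ETo,
#' plus the relative change `(future - baseline)/baseline * 100`.
#'
#' @param baseline,future Annual-aggregate tables from [annual_aggregates()].
#' @return A `data.frame` with one row per variable and columns
#'   `variable, baseline_mean, future_mean, relative_change_pct`.
#' @export
climate_change_summary <- function(baseline, future) {
  vars <- c("annual_precip", "annual_gdd", "annual_eto")
  for (v in vars) {
    if (is.null(baseline[[v]]) || is.null(future[[v]])) {
      stopf("both periods must carry column '%s'", v)
    }
  }
  b <- vapply(vars, function(v) mean(baseline[[v]]), numeric(1))
  f <- vapply(vars, function(v) mean(future[[v]]), numeric(1))
  data.frame(variable = vars,
             baseline_mean = as.numeric(b),
             future_mean = as.numeric(f),
             relative_change_pct = as.numeric((f - b) / b * 100),
             row.names = NULL)
}
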