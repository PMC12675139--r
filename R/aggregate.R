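#' Ensemble median across members
#'
#' Per-cell median across ensemble members; chosen over the mean for
#' robustness in small ensembles. Even member counts average the two
#' central order statistics.
#'
#' @param x A numeric vector (one cell, members along the vector) or a
#'   matrix/data.frame with cells in rows and members in columns.
#' @return The member-wise median (scalar or per-row vector).
#' @export
ensemble_median <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (ncol(x) < 1L) stopf("need at least one ensemble member")
    return(apply(x, 1, stats::median, na.rm = FALSE))
  }
  if (length(x) < 1L) stopf("need at least one ensemble member")
  stats::median(x)
}

#' Cycle-completion inclusion mask
#'
#' A cell is included in the analysis only when every ensemble member has at
#' least `min_years` years with a completed crop cycle in the period
#' (boundary inclusive).
#'
#' @param complete_counts Matrix of complete-year counts, cells in rows and
#'   members in columns; or a 3-d logical array `[cell, year, member]` of
#'   per-year completion flags.
#' @param min_years Minimum complete years required in all members (5).
#' @return Logical vector, one flag per cell.
#' @export
inclusion_mask <- function(complete_counts, min_years = 5) {
  assert_number(min_years, "min_years", 0, Inf)
  if (is.array(complete_counts) && length(dim(complete_counts)) == 3L) {
    complete_counts <- apply(complete_counts, c(1, 3), sum)
  }
  if (is.data.frame(complete_counts)) {
    complete_counts <- as.matrix(complete_counts)
  }
  if (!is.matrix(complete_counts)) {
    complete_counts <- matrix(complete_counts, nrow = 1)
  }
  apply(complete_counts >= min_years, 1, all)
}

#' Crossmask two scenario masks
#'
#' Restricts comparisons to cells valid (enough completed cycles) in both
#' the baseline and the future scenario: the logical AND of the two masks.
#' The individual masks remain available for single-scenario (suitability)
#' views.
#'
#' @param baseline_mask,future_mask Logical vectors over the same cell set
#'   (name-checked when named).
#' @return Logical vector: the joint mask.
#' @export
crossmask <- function(baseline_mask, future_mask) {
  if (length(baseline_mask) != length(future_mask)) {
    stopf("masks cover different cell sets (lengths %d vs %d)",
          length(baseline_mask), length(future_mask))
  }
  if (!is.null(names(baseline_mask)) && !is.null(names(future_mask)) &&
      any(names(baseline_mask) != names(future_mask))) {
    stopf("masks cover different cell sets (names differ)")
  }
  baseline_mask & future_mask
}

#' Relative change between baseline and future fields
#'
#' `(future - baseline) / baseline * 100` per cell. Cells with zero baseline
#' are undefined and flagged as `NA` with a warning.
#'
#' @param baseline,future Numeric fields over the same cells.
#' @return Percent change per cell.
#' @export
relative_change <- function(baseline, future) {
  if (length(baseline) != length(future)) {
    stopf("fields cover different cell sets")
  }
  bad <- !is.na(baseline) & baseline == 0
  if (any(bad)) {
    warning(sprintf("relative change undefined for %d cell(s) with zero baseline",
                    sum(bad)), call. = FALSE)
  }
  out <- (future - baseline) / baseline * 100
  out[bad] <- NA_real_
  out
}

#' Suitability classification of mean rainfed yield
#'
#' Mean actual yield below 4 ton/ha marks a cell unsuitable for rainfed
#' production; above 7 ton/ha marks biophysically profitable production;
#' boundary values fall in the middle class (strict inequalities).
#'
#' @param mean_ya Mean Ya over complete years, ton/ha; vectorised.
#' @param unsuitable_below,profitable_above Thresholds, ton/ha (4 and 7).
#' @return Factor with levels `unsuitable`, `suitable`, `profitable`.
#' @export
classify_suitability <- function(mean_ya, unsuitable_below = 4,
                                 profitable_above = 7) {
  out <- ifelse(mean_ya < unsuitable_below, "unsuitable",
                ifelse(mean_ya > profitable_above, "profitable", "suitable"))
  factor(out, levels = c("unsuitable", "suitable", "profitable"))
}

#' Count crop failures in a yield series
#'
#' A crop failure is a year with actual yield strictly below the threshold.
#' Years with incomplete cycles carry zero yield and therefore count as
#' failures (no harvestable grain), even though they are excluded from
#' mean-yield statistics; set `count_incomplete = FALSE` to drop them
#' instead.
#'
#' @param ya_years Per-year actual yields, ton/ha (incomplete years as 0).
#' @param threshold Failure threshold, ton/ha (4).
#' @param complete Optional logical vector of per-year completion flags,
#'   used only when `count_incomplete = FALSE`.
#' @param count_incomplete Count incomplete years as failures (default
#'   `TRUE`).
#' @return Integer failure count.
#' @export
count_failures <- function(ya_years, threshold = 4, complete = NULL,
                           count_incomplete = TRUE) {
  fail <- ya_years < threshold
  if (!count_incomplete && !is.null(complete)) fail <- fail & complete
  sum(fail)
}

#' Spatial domain summary
#'
#' Spatial mean, median and quartiles (linear interpolation between order
#' statistics) of a per-cell field over the masked domain, optionally
#' excluding cells below a mean-yield cutoff (to focus on the viable
#' production area). Spatial means are unweighted.
#'
#' @param values Per-cell numeric field.
#' @param mask Optional logical inclusion mask.
#' @param exclude_below Optional cutoff: cells with `values` below it are
#'   dropped before summarising.
#' @return A one-row `data.frame` with `n, mean, median, q25, q75`.
#' @export
domain_summary <- function(values, mask = NULL, exclude_below = NULL) {
  x <- values
  if (!is.null(mask)) {
    if (length(mask) != length(x)) stopf("mask length mismatch")
    x <- x[mask]
  }
  x <- x[!is.na(x)]
  if (!is.null(exclude_below)) x <- x[x >= exclude_below]
  if (length(x) == 0L) stopf("no cells remain after masking/exclusion")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(x), mean = mean(x), median = q[2],
             q25 = q[1], q75 = q[3])
}
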