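#' Build a latitude-gradient study grid
#'
#' Generates a simple set of 0.5-degree grid cells spanning a latitude range
#' with climatology varying along the gradient: annual mean temperature
#' falls with latitude, the seasonal cycle grows slightly more continental,
#' and wet-day frequency increases northward (the south is drier). These are
#' the per-cell inputs of the synthetic weather generator.
#'
#' @param n_cells Number of cells.
#' @param lat_min,lat_max Latitude range, degrees north.
#' @param lon Longitude assigned to all cells, degrees east.
#' @return A `data.frame` with one row per cell: `cell_id, lat, lon,
#'   elevation` plus the climate-spec fields.
#' @export
make_latitude_grid <- function(n_cells = 20, lat_min = 38, lat_max = 55,
                               lon = 10) {
  assert_count(n_cells, "n_cells")
  lat <- if (n_cells == 1) (lat_min + lat_max) / 2 else
    seq(lat_min, lat_max, length.out = n_cells)
  lat <- round(lat * 2) / 2  # snap to the 0.5-degree lattice
  data.frame(cell_id = seq_len(n_cells),
             lat = lat,
             lon = lon,
             elevation = 100,
             annual_mean_temp = 40 - 0.62 * lat,
             seasonal_amplitude = 8.5 + 0.08 * (lat - 45),
             diurnal_range = 9,
             anomaly_sd = 3,
             anomaly_autocorr = 0.7,
             wet_day_prob = clamp(0.22 + 0.007 * (lat - 34), 0.05, 0.6),
             wet_persistence = 0.6,
             mean_wet_amount = 5.5,
             rh_mean = 75,
             wind10_mean = 3.5)
}

#' Climate scenario definition
#'
#' Scenario knobs applied on top of a cell's climatology: a uniform warming
#' offset, a multiplicative precipitation scaling, and a linear CO2
#' trajectory anchored at the scenario's first year.
#'
#' @param delta_T Warming offset, degrees C.
#' @param precip_factor Precipitation multiplier.
#' @param co2_start CO2 in the first scenario year, ppm.
#' @param co2_trend CO2 trend, ppm/year.
#' @param start_year First calendar year of the period.
#' @return A named list of class `scenario_spec`.
#' @export
scenario_spec <- function(delta_T = 0, precip_factor = 1,
                          co2_start = 354, co2_trend = 1.7,
                          start_year = 1985L) {
  assert_number(delta_T, "delta_T", -20, 20)
  assert_number(precip_factor, "precip_factor", 0, Inf, strict_lower = TRUE)
  assert_number(co2_start, "co2_start", 0, Inf, strict_lower = TRUE)
  assert_number(co2_trend, "co2_trend", -10, 50)
  start_year <- assert_count(start_year, "start_year")
  structure(list(delta_T = delta_T, precip_factor = precip_factor,
                 co2_start = co2_start, co2_trend = co2_trend,
                 start_year = start_year),
            class = "scenario_spec")
}

#' Full experiment configuration
#'
#' Bundles everything one experiment needs: the study grid, the named
#' climate scenarios (the first is the baseline), ensemble size and period
#' length, crop, soil, sowing rule, the three management regimes' settings,
#' the masking and classification thresholds, and the global seed from which
#' all member/cell sub-seeds are derived.
#'
#' @param grid Study grid, see [make_latitude_grid()].
#' @param scenarios Named list of [scenario_spec()]s; must include
#'   `"baseline"`. Defaults to the 1985-2014 baseline plus a +2 degree C,
#'   slightly drier, CO2-enriched 2030-2059 scenario.
#' @param n_members Ensemble size (default 5).
#' @param n_years Years per period (default 30).
#' @param crop,soil,rule Crop, soil and sowing-rule objects.
#' @param fertility_stress Ya-regime fertility stress, percent (30).
#' @param irrigation_trigger_fraction Yp irrigation trigger (0.5 of RAW).
#' @param min_years Complete-year masking threshold (5).
#' @param failure_threshold Crop-failure yield threshold, ton/ha (4).
#' @param unsuitable_below,profitable_above Suitability thresholds, ton/ha.
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(grid = make_latitude_grid(),
                       scenarios = list(
                         baseline = scenario_spec(),
                         future = scenario_spec(delta_T = 2,
                                                precip_factor = 0.95,
                                                co2_start = 450,
                                                co2_trend = 3,
                                                start_year = 2030L)),
                       n_members = 5,
                       n_years = 30,
                       crop = crop_parameters(),
                       soil = soil_profile(),
                       rule = sowing_rule(),
                       fertility_stress = 30,
                       irrigation_trigger_fraction = 0.5,
                       min_years = 5,
                       failure_threshold = 4,
                       unsuitable_below = 4,
                       profitable_above = 7,
                       seed = 1L) {
  cfg <- assemble_config(grid, scenarios, n_members, n_years, crop, soil,
                         rule, fertility_stress,
                         irrigation_trigger_fraction, min_years,
                         failure_threshold, unsuitable_below,
                         profitable_above, seed)
  rep <- validate_config(cfg)
  if (nrow(rep) > 0) {
    stopf("invalid run_config:\n%s",
          paste(sprintf("  %s: %s", rep$field, rep$message), collapse = "\n"))
  }
  cfg
}

assemble_config <- function(grid, scenarios, n_members, n_years, crop, soil,
                            rule, fertility_stress,
                            irrigation_trigger_fraction, min_years,
                            failure_threshold, unsuitable_below,
                            profitable_above, seed) {
  structure(list(grid = grid, scenarios = scenarios,
                 n_members = n_members, n_years = n_years,
                 crop = crop, soil = soil, rule = rule,
                 fertility_stress = fertility_stress,
                 irrigation_trigger_fraction = irrigation_trigger_fraction,
                 min_years = min_years,
                 failure_threshold = failure_threshold,
                 unsuitable_below = unsuitable_below,
                 profitable_above = profitable_above,
                 seed = seed),
            class = "run_config")
}

#' Validate an experiment configuration
#'
#' Checks every sub-configuration against its own module's invariants and
#' lists each violation with its field path. Accepts a `run_config` object
#' or the path of a YAML config file.
#'
#' @param config A `run_config`, a plain list, or a YAML file path.
#' @return A `data.frame` with columns `field` and `message` (zero rows when
#'   valid) and attribute `"valid"`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config, validate = FALSE)
  problems <- list()
  note <- function(field, message) {
    problems[[length(problems) + 1L]] <<- data.frame(field = field,
                                                     message = message)
  }
  try_field <- function(field, expr) {
    tryCatch(expr, error = function(e) note(field, conditionMessage(e)))
  }

  grid_cols <- c("cell_id", "lat", "lon", "elevation", "annual_mean_temp",
                 "seasonal_amplitude", "diurnal_range", "anomaly_sd",
                 "anomaly_autocorr", "wet_day_prob", "wet_persistence",
                 "mean_wet_amount", "rh_mean", "wind10_mean")
  if (!is.data.frame(config$grid)) {
    note("grid", "must be a data.frame")
  } else {
    missing_cols <- setdiff(grid_cols, names(config$grid))
    if (length(missing_cols)) {
      note("grid", paste("missing columns:",
                         paste(missing_cols, collapse = ", ")))
    }
  }
  if (!is.list(config$scenarios) || is.null(config$scenarios$baseline)) {
    note("scenarios", "must be a named list containing 'baseline'")
  } else {
    for (nm in names(config$scenarios)) {
      sc <- config$scenarios[[nm]]
      try_field(paste0("scenarios$", nm), do.call(scenario_spec, unclass(sc)))
    }
  }
  try_field("n_members", assert_count(config$n_members, "n_members"))
  try_field("n_years", assert_count(config$n_years, "n_years"))
  try_field("crop", do.call(crop_parameters, unclass(config$crop)))
  try_field("soil", do.call(soil_profile, unclass(config$soil)))
  try_field("rule", do.call(sowing_rule, unclass(config$rule)))
  try_field("fertility_stress",
            assert_number(config$fertility_stress, "fertility_stress", 0, 100))
  try_field("irrigation_trigger_fraction",
            assert_number(config$irrigation_trigger_fraction,
                          "irrigation_trigger_fraction", 0, 1,
                          strict_lower = TRUE))
  try_field("min_years",
            assert_number(config$min_years, "min_years", 0, Inf))
  try_field("failure_threshold",
            assert_number(config$failure_threshold, "failure_threshold",
                          0, Inf))
  try_field("seed", assert_count(config$seed, "seed", lower = 0L))
  # per-cell climate specs must validate too
  if (is.data.frame(config$grid) &&
      all(grid_cols %in% names(config$grid)) &&
      !is.null(config$scenarios$baseline)) {
    for (r in seq_len(nrow(config$grid))) {
      try_field(sprintf("grid[%d]", r),
                cell_climate_spec(config$grid[r, ],
                                  config$scenarios$baseline, seed = 1L))
    }
  }
  out <- if (length(problems)) do.call(rbind, problems) else
    data.frame(field = character(), message = character())
  attr(out, "valid") <- nrow(out) == 0L
  out
}

#' Read an experiment configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the [run_config()]
#' arguments (`grid` as a list of cell records, `scenarios`, `crop`, `soil`,
#' `rule`, scalars); missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @param validate Validate the assembled config (default `TRUE`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, validate = TRUE) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stopf("unparseable config file '%s': %s", path, conditionMessage(e))
  })
  if (!is.list(raw)) stopf("unparseable config file '%s': not a mapping", path)
  # assemble raw values without validation, falling back to defaults
  defaults <- formals(run_config)
  get_or <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else
    default
  grid <- if (!is.null(raw$grid)) {
    do.call(rbind, lapply(raw$grid, as.data.frame))
  } else make_latitude_grid()
  scenarios <- if (!is.null(raw$scenarios)) {
    lapply(raw$scenarios, function(s) {
      tryCatch(do.call(scenario_spec, s), error = function(e) s)
    })
  } else eval(defaults$scenarios)
  merge_obj <- function(key, ctor, default) {
    if (is.null(raw[[key]])) return(default)
    tryCatch(do.call(ctor, raw[[key]]), error = function(e) raw[[key]])
  }
  cfg <- assemble_config(
    grid, scenarios,
    get_or("n_members", 5), get_or("n_years", 30),
    merge_obj("crop", crop_parameters, crop_parameters()),
    merge_obj("soil", soil_profile, soil_profile()),
    merge_obj("rule", sowing_rule, sowing_rule()),
    get_or("fertility_stress", 30),
    get_or("irrigation_trigger_fraction", 0.5),
    get_or("min_years", 5), get_or("failure_threshold", 4),
    get_or("unsuitable_below", 4), get_or("profitable_above", 7),
    get_or("seed", 1L))
  if (validate) {
    rep <- validate_config(cfg)
    if (nrow(rep) > 0) {
      stopf("invalid config '%s':\n%s", path,
            paste(sprintf("  %s: %s", rep$field, rep$message),
                  collapse = "\n"))
    }
  }
  cfg
}

# Assemble the climate_spec of one grid cell under one scenario.
cell_climate_spec <- function(cell, scenario, seed) {
  climate_spec(latitude = cell$lat,
               annual_mean_temp = cell$annual_mean_temp,
               seasonal_amplitude = cell$seasonal_amplitude,
               diurnal_range = cell$diurnal_range,
               anomaly_sd = cell$anomaly_sd,
               anomaly_autocorr = cell$anomaly_autocorr,
               wet_day_prob = cell$wet_day_prob,
               wet_persistence = cell$wet_persistence,
               mean_wet_amount = cell$mean_wet_amount,
               rh_mean = cell$rh_mean,
               wind10_mean = cell$wind10_mean,
               co2_start = scenario$co2_start,
               delta_T = scenario$delta_T,
               precip_factor = scenario$precip_factor,
               co2_trend = scenario$co2_trend,
               seed = seed)
}

#' Run the full experiment
#'
#' Orchestrates the whole pipeline from one configuration: for every
#' scenario, ensemble member and grid cell, generates synthetic daily
#' weather, derives ETo and GDD, finds the temperature-dependent sowing
#' date per year, runs the three management regimes, and aggregates the
#' per-year results into cell statistics, ensemble medians,
#' completion/inclusion masks, crossmasked relative-change fields,
#' suitability classes, crop-failure counts and domain summaries. Fully
#' deterministic given the config's global seed: every member/cell weather
#' stream uses a sub-seed derived from it.
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory: when given, writes the tabular
#'   outputs as CSV plus a machine-readable JSON run manifest.
#' @return A list with elements `seasons` (per cell-year regime results),
#'   `cell_stats` (per scenario x member x cell), `median_stats` (ensemble
#'   medians per scenario x cell), `masks` (per-scenario inclusion masks and
#'   crossmasks vs baseline), `changes` (crossmasked relative-change fields
#'   per future scenario), `classification` (suitability and failures per
#'   scenario), and `summaries` (domain summaries).
#' @export
run_experiment <- function(config = run_config(), output_dir = NULL) {
  if (!inherits(config, "run_config")) stopf("'config' must be a run_config")
  grid <- config$grid
  n_cells <- nrow(grid)
  scen_names <- names(config$scenarios)

  season_rows <- list()
  stat_rows <- list()

  for (s_idx in seq_along(config$scenarios)) {
    scen <- config$scenarios[[s_idx]]
    scen_name <- scen_names[s_idx]
    for (m in seq_len(config$n_members)) {
      for (c_idx in seq_len(n_cells)) {
        cell <- grid[c_idx, ]
        spec0 <- cell_climate_spec(cell, scen, seed = 1L)
        spec_m <- member_spec(spec0, m, config$n_members)
        spec_m$seed <- derive_seed(config$seed, s_idx, m, c_idx)
        wx <- generate_weather(spec_m, config$n_years, scen$start_year)
        wx <- derive_climate(wx, latitude = cell$lat,
                             elevation = cell$elevation,
                             tbase = config$crop$tbase,
                             tupper = config$crop$tupper)
        yrs <- year_of(wx$date)
        triplets <- vector("list", config$n_years)
        for (y_idx in seq_len(config$n_years)) {
          yr <- scen$start_year + y_idx - 1L
          wx_y <- wx[yrs == yr, , drop = FALSE]
          sowing <- find_sowing_date(wx_y, config$rule)
          tri <- run_regimes(wx_y, config$crop, config$soil, sowing,
                             fertility_stress = config$fertility_stress,
                             irrigation_trigger_fraction =
                               config$irrigation_trigger_fraction)
          triplets[[y_idx]] <- tri
          season_rows[[length(season_rows) + 1L]] <- data.frame(
            scenario = scen_name, member = m, cell_id = cell$cell_id,
            lat = cell$lat, lon = cell$lon, year = yr,
            sowing_doy = doy_of(tri$sowing_date),
            complete = tri$complete,
            cycle_length = ifelse(is.na(tri$cycle_length), NA_integer_,
                                  tri$cycle_length),
            ya = tri$ya, yw = tri$yw, yp = tri$yp,
            etc_a = tri$etc_a, etc_w = tri$etc_w, etc_p = tri$etc_p,
            irrigation_p = tri$seasons$yp$irrigation_sum)
        }
        st <- cell_statistics(triplets,
                              failure_threshold = config$failure_threshold)
        stat_rows[[length(stat_rows) + 1L]] <- cbind(
          data.frame(scenario = scen_name, member = m,
                     cell_id = cell$cell_id, lat = cell$lat,
                     lon = cell$lon), st)
      }
    }
  }

  seasons <- do.call(rbind, season_rows)
  cell_stats <- do.call(rbind, stat_rows)

  # ensemble medians per scenario x cell
  stat_cols <- c("mean_ya", "mean_yw", "mean_yp", "sd_ya", "sd_yw", "sd_yp",
                 "ygw", "ygp", "wpa", "wpw", "wpp", "mean_sowing_doy",
                 "mean_cycle_length", "n_complete_years", "n_failures")
  median_rows <- list()
  masks <- list()
  for (scen_name in scen_names) {
    sub <- cell_stats[cell_stats$scenario == scen_name, ]
    med <- data.frame(scenario = scen_name,
                      cell_id = grid$cell_id, lat = grid$lat, lon = grid$lon)
    counts <- matrix(NA_real_, n_cells, config$n_members)
    for (col in stat_cols) {
      mat <- matrix(NA_real_, n_cells, config$n_members)
      for (m in seq_len(config$n_members)) {
        sm <- sub[sub$member == m, ]
        mat[match(sm$cell_id, grid$cell_id), m] <- sm[[col]]
      }
      if (col == "n_complete_years") counts <- mat
      med[[col]] <- ensemble_median(mat)
    }
    masks[[scen_name]] <- inclusion_mask(counts, config$min_years)
    names(masks[[scen_name]]) <- as.character(grid$cell_id)
    median_rows[[scen_name]] <- med
  }
  median_stats <- do.call(rbind, median_rows)
  rownames(median_stats) <- NULL

  # crossmasked relative changes vs baseline
  base_med <- median_rows[["baseline"]]
  changes <- list()
  crossmasks <- list()
  for (scen_name in setdiff(scen_names, "baseline")) {
    cm <- crossmask(masks[["baseline"]], masks[[scen_name]])
    crossmasks[[scen_name]] <- cm
    fut <- median_rows[[scen_name]]
    ch <- data.frame(scenario = scen_name, cell_id = grid$cell_id,
                     lat = grid$lat, lon = grid$lon, crossmasked = cm)
    for (col in c("mean_ya", "mean_yw", "mean_yp", "wpa",
                  "mean_sowing_doy", "mean_cycle_length")) {
      ch[[paste0("dch_", col)]] <- ifelse(
        cm, relative_change(base_med[[col]], fut[[col]]), NA_real_)
      ch[[paste0("diff_", col)]] <- ifelse(
        cm, fut[[col]] - base_med[[col]], NA_real_)
    }
    changes[[scen_name]] <- ch
  }

  classification <- do.call(rbind, lapply(scen_names, function(scen_name) {
    med <- median_rows[[scen_name]]
    data.frame(scenario = scen_name, cell_id = grid$cell_id,
               lat = grid$lat, lon = grid$lon,
               included = masks[[scen_name]],
               suitability = classify_suitability(
                 med$mean_ya, config$unsuitable_below,
                 config$profitable_above),
               n_failures = med$n_failures)
  }))

  summaries <- do.call(rbind, lapply(scen_names, function(scen_name) {
    med <- median_rows[[scen_name]]
    msk <- masks[[scen_name]]
    if (!any(msk)) return(NULL)
    do.call(rbind, lapply(c("mean_ya", "mean_yw", "mean_yp"), function(col) {
      cbind(data.frame(scenario = scen_name, variable = col),
            domain_summary(med[[col]], mask = msk))
    }))
  }))
  rownames(summaries) <- NULL

  out <- list(seasons = seasons, cell_stats = cell_stats,
              median_stats = median_stats, masks = masks,
              crossmasks = crossmasks, changes = changes,
              classification = classification, summaries = summaries,
              config = config)

  if (!is.null(output_dir)) write_experiment(out, output_dir)
  out
}

# Polynomial rolling hash of the deparsed config, for the run manifest.
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

write_experiment <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(output_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  w(result$seasons, "seasons")
  w(result$cell_stats, "cell_stats")
  w(result$median_stats, "median_stats")
  w(result$classification, "classification")
  w(result$summaries, "summaries")
  if (length(result$changes)) w(do.call(rbind, result$changes), "changes")
  mask_df <- data.frame(cell_id = as.integer(names(result$masks[[1]])))
  for (nm in names(result$masks)) mask_df[[nm]] <- result$masks[[nm]]
  w(mask_df, "masks")
  cfg <- result$config
  manifest <- list(
    package = "maizegap",
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_members = cfg$n_members,
    n_years = cfg$n_years,
    n_cells = nrow(cfg$grid),
    scenarios = lapply(cfg$scenarios, unclass),
    periods = lapply(cfg$scenarios, function(s) {
      c(s$start_year, s$start_year + cfg$n_years - 1)
    }))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}
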