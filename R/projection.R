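#' Scenario specification
#'
#' Names a climate input for projection: the historical baseline or one of
#' the four Representative Concentration Pathways, the file holding its
#' daily temperature grid, the target year, and the calendar window (the
#' Christmas week by default) whose mean drives the maps.
#'
#' @param name one of `"historical"`, `"RCP2.6"`, `"RCP4.5"`, `"RCP6.0"`,
#'   `"RCP8.5"`.
#' @param climate_path NetCDF file path.
#' @param target_year year whose window is averaged (e.g. 1999 or 2099).
#' @param window a [calendar_window()]; default [christmas_window()].
#' @param variable_name NetCDF variable, default `"tasAdjust"`.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, climate_path, target_year,
                          window = christmas_window(),
                          variable_name = "tasAdjust") {
  allowed <- c("historical", "RCP2.6", "RCP4.5", "RCP6.0", "RCP8.5")
  if (!name %in% allowed)
    rp_stop("rpclim_validation_error",
            sprintf("scenario name '%s' not one of: %s", name,
                    paste(allowed, collapse = ", ")))
  structure(list(name = name, climate_path = climate_path,
                 target_year = as.integer(target_year), window = window,
                 variable_name = variable_name),
            class = "scenario_spec")
}

#' Project prevalence and attack frequency onto a climate scenario
#'
#' Averages the scenario's daily grid over its calendar window and applies
#' the two calibrated models cell by cell: the linear prevalence model
#' (clamped to 0-100 percent) and the Poisson attack model (weekly frequency
#' `7 exp(x'beta)`, zeroed at and above the no-attack ceiling). Masked ocean
#' cells stay masked.
#'
#' @param scenario a [scenario_spec()].
#' @param prevalence_fit a [fit_prevalence()] result.
#' @param severity_fit a [fit_poisson()] (or imported) result.
#' @param grid optional pre-loaded [temperature_grid()]; when `NULL` the
#'   scenario's `climate_path` is read.
#' @return object of class `projection_maps` with fields `scenario`,
#'   `lat`, `lon`, `mean_temp`, `prevalence`, `weekly_attacks` (all
#'   `[lat, lon]`), and `NULL` delta fields until
#'   [compare_to_baseline()] fills them.
#' @export
project_scenario <- function(scenario, prevalence_fit, severity_fit, grid = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (is.null(grid))
    grid <- read_temperature_grid(scenario$climate_path, scenario$variable_name)
  mt <- window_mean(grid, scenario$window, scenario$target_year)
  prev <- predict_prevalence(prevalence_fit, mt$values)
  weekly <- predict_weekly_attacks(severity_fit, mt$values)
  structure(
    list(scenario = scenario, lat = mt$lat, lon = mt$lon,
         mean_temp = mt$values, prevalence = prev, weekly_attacks = weekly,
         delta_prevalence = NULL, delta_weekly = NULL),
    class = "projection_maps")
}

#' @export
print.projection_maps <- function(x, ...) {
  cat(sprintf("<projection_maps> %s, year %d, %d x %d grid\n",
              x$scenario$name, x$scenario$target_year,
              length(x$lat), length(x$lon)))
  cat(sprintf("  area-weighted means: temp %.2f degC, prevalence %.2f%%, %.2f attacks/week\n",
              area_weighted_mean(x$mean_temp, x$lat),
              area_weighted_mean(x$prevalence, x$lat),
              area_weighted_mean(x$weekly_attacks, x$lat)))
  invisible(x)
}

#' Difference a scenario projection against the baseline
#'
#' Fills the scenario's cellwise delta fields (scenario minus baseline) and
#' attaches a one-row summary of area-weighted (cosine-latitude) means.
#'
#' @param baseline,scenario [project_scenario()] results on identical grids.
#' @return `scenario` with `delta_prevalence`, `delta_weekly`,
#'   `delta_mean_temp` filled and a `summary` data frame attached.
#' @export
compare_to_baseline <- function(baseline, scenario) {
  stopifnot(inherits(baseline, "projection_maps"), inherits(scenario, "projection_maps"))
  if (!isTRUE(all.equal(baseline$lat, scenario$lat)) ||
      !isTRUE(all.equal(baseline$lon, scenario$lon)))
    rp_stop("rpclim_alignment_error", "baseline and scenario are on different grids")
  scenario$delta_mean_temp <- scenario$mean_temp - baseline$mean_temp
  scenario$delta_prevalence <- scenario$prevalence - baseline$prevalence
  scenario$delta_weekly <- scenario$weekly_attacks - baseline$weekly_attacks
  scenario$summary <- data.frame(
    scenario = scenario$scenario$name,
    target_year = scenario$scenario$target_year,
    mean_temp = area_weighted_mean(scenario$mean_temp, scenario$lat),
    mean_prevalence = area_weighted_mean(scenario$prevalence, scenario$lat),
    mean_weekly_attacks = area_weighted_mean(scenario$weekly_attacks, scenario$lat),
    delta_mean_temp = area_weighted_mean(scenario$delta_mean_temp, scenario$lat),
    delta_prevalence = area_weighted_mean(scenario$delta_prevalence, scenario$lat),
    delta_weekly_attacks = area_weighted_mean(scenario$delta_weekly, scenario$lat),
    stringsAsFactors = FALSE)
  scenario
}

#' Cosine-latitude area-weighted mean of a gridded field
#'
#' @param values `[lat, lon]` matrix, `NA` ignored.
#' @param lat latitude centers in degrees.
#' @return scalar weighted mean.
#' @export
area_weighted_mean <- function(values, lat) {
  w <- matrix(cos(lat * pi / 180), nrow = length(lat), ncol = ncol(values))
  ok <- !is.na(values)
  if (!any(ok)) return(NA_real_)
  sum(values[ok] * w[ok]) / sum(w[ok])
}

#' Write projection maps to CSV and NetCDF
#'
#' The CSV holds one row per cell (`lat, lon, mean_temp, prevalence,
#' weekly_attacks, daily_attacks` and, when present, the delta fields);
#' the NetCDF carries the same fields on the input grid.
#'
#' @param maps a [project_scenario()] / [compare_to_baseline()] result.
#' @param csv_path,nc_path output paths (`NULL` to skip either).
#' @export
write_projection_maps <- function(maps, csv_path = NULL, nc_path = NULL) {
  stopifnot(inherits(maps, "projection_maps"))
  fields <- list(mean_temp = maps$mean_temp,
                 prevalence = maps$prevalence,
                 weekly_attacks = maps$weekly_attacks,
                 daily_attacks = maps$weekly_attacks / 7)
  if (!is.null(maps$delta_prevalence)) {
    fields$delta_mean_temp <- maps$delta_mean_temp
    fields$delta_prevalence <- maps$delta_prevalence
    fields$delta_weekly_attacks <- maps$delta_weekly
  }
  if (!is.null(csv_path)) {
    df <- data.frame(lat = rep(maps$lat, times = length(maps$lon)),
                     lon = rep(maps$lon, each = length(maps$lat)))
    for (nm in names(fields)) df[[nm]] <- as.vector(fields[[nm]])
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(nc_path)) {
    dlon <- ncdf4::ncdim_def("lon", "degrees_east", maps$lon)
    dlat <- ncdf4::ncdim_def("lat", "degrees_north", maps$lat)
    units <- c(mean_temp = "degC", prevalence = "percent",
               weekly_attacks = "attacks week-1", daily_attacks = "attacks day-1",
               delta_mean_temp = "degC", delta_prevalence = "percent",
               delta_weekly_attacks = "attacks week-1")
    vars <- lapply(names(fields), function(nm)
      ncdf4::ncvar_def(nm, units[[nm]], list(dlon, dlat), missval = 1e20, prec = "double"))
    nc <- ncdf4::nc_create(nc_path, vars)
    on.exit(ncdf4::nc_close(nc))
    for (i in seq_along(fields))
      ncdf4::ncvar_put(nc, vars[[i]], t(fields[[i]]))
  }
  invisible(maps)
}
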