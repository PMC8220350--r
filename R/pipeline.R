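in_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
    stop(e)
  })
}

config_window <- function(x, default) {
  if (is.null(x)) return(default)
  calendar_window(x$start, x$end)
}

#' Run the full projection pipeline from a config file
#'
#' Executes assign -> fit -> project -> compare end to end: links each
#' prevalence survey to its preceding-winter mean temperature, fits the
#' linear prevalence model, fits (or imports) the Poisson attack model,
#' projects both onto the baseline Christmas and every scenario Christmas,
#' and differences the scenarios against the baseline. Writes per-scenario
#' maps (CSV and NetCDF), both fits (JSON), an area-weighted summary table
#' (CSV), and a run log with the seed, versions and all resolved parameters.
#' Reruns with the same config produce byte-identical CSV output.
#'
#' @param config_path YAML (or JSON) configuration file. Required keys:
#'   `output_dir`, `study_table`, `diaries` *or* `severity_coefficients`,
#'   `climate` (with `historical` and a named `scenarios` map of RCP name ->
#'   file), `baseline_year`, `target_year`. Optional: `seed`,
#'   `climate$variable` (default `"tasAdjust"`), `winter_window`,
#'   `south_winter_window`, `christmas_window` (each `{start, end}` as
#'   `"MM-DD"`), `weighting`, `covariates`, `patient_effects`,
#'   `attack_threshold_temp`, `max_radius`.
#' @return invisibly, a list with the fits, the baseline and scenario maps,
#'   and the summary data frame.
#' @export
run_pipeline <- function(config_path) {
  if (!file.exists(config_path))
    rp_stop("rpclim_io_error", sprintf("config not found: %s", config_path))
  cfg <- if (grepl("\\.json$", config_path, ignore.case = TRUE))
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  else yaml::read_yaml(config_path)

  # -- startup validation: every referenced file must exist before any work
  in_stage("startup", {
    for (key in c("output_dir", "study_table", "climate", "baseline_year", "target_year"))
      if (is.null(cfg[[key]]))
        rp_stop("rpclim_validation_error", sprintf("config missing key '%s'", key))
    if (is.null(cfg$diaries) && is.null(cfg$severity_coefficients))
      rp_stop("rpclim_validation_error",
              "config must name either 'diaries' or 'severity_coefficients'")
    if (is.null(cfg$climate$historical) || is.null(cfg$climate$scenarios) ||
        is.null(names(cfg$climate$scenarios)))
      rp_stop("rpclim_validation_error",
              "config 'climate' must name 'historical' and a named 'scenarios' map")
    paths <- c(cfg$study_table, cfg$diaries, cfg$severity_coefficients,
               cfg$climate$historical, unlist(cfg$climate$scenarios))
    gone <- paths[!file.exists(paths)]
    if (length(gone))
      rp_stop("rpclim_validation_error",
              sprintf("input file(s) not found: %s", paste(gone, collapse = ", ")))
  })

  seed <- cfg$seed %||% 1L
  variable <- cfg$climate$variable %||% "tasAdjust"
  wwin <- config_window(cfg$winter_window, winter_window())
  swin <- if (!is.null(cfg$south_winter_window))
    config_window(cfg$south_winter_window, austral_winter_window()) else NULL
  xwin <- config_window(cfg$christmas_window, christmas_window())
  max_radius <- cfg$max_radius %||% 3L
  threshold <- cfg$attack_threshold_temp %||% 13
  covariates <- cfg$covariates %||% "temperature"

  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  studies <- in_stage("read-studies", read_study_table(cfg$study_table))
  hist_grid <- in_stage("read-climate",
                        read_temperature_grid(cfg$climate$historical, variable))
  studies <- in_stage("assign-winter-temps",
                      assign_winter_temps(studies, hist_grid, window = wwin,
                                          south_window = swin, max_radius = max_radius))
  prev_fit <- in_stage("fit-prevalence",
                       fit_prevalence(studies, weighting = cfg$weighting %||% "none"))
  sev_fit <- in_stage("fit-severity", {
    if (!is.null(cfg$diaries)) {
      d <- read_attack_diaries(cfg$diaries)
      fit_poisson(d, covariate_names = covariates,
                  patient_effects = isTRUE(cfg$patient_effects),
                  attack_threshold_temp = threshold)
    } else {
      f <- read_severity_fit(cfg$severity_coefficients)
      f$attack_threshold_temp <- threshold
      f
    }
  })

  baseline_spec <- scenario_spec("historical", cfg$climate$historical,
                                 cfg$baseline_year, window = xwin,
                                 variable_name = variable)
  baseline <- in_stage("project-baseline",
                       project_scenario(baseline_spec, prev_fit, sev_fit,
                                        grid = hist_grid))
  scen_maps <- list()
  for (nm in names(cfg$climate$scenarios)) {
    spec <- scenario_spec(nm, cfg$climate$scenarios[[nm]], cfg$target_year,
                          window = xwin, variable_name = variable)
    m <- in_stage(paste0("project-", nm),
                  project_scenario(spec, prev_fit, sev_fit))
    scen_maps[[nm]] <- in_stage(paste0("compare-", nm),
                                compare_to_baseline(baseline, m))
  }

  in_stage("write-outputs", {
    slug <- function(x) gsub("[^a-z0-9]+", "", tolower(x))
    write_prevalence_fit(prev_fit, file.path(out, "prevalence_fit.json"))
    write_severity_fit(sev_fit, file.path(out, "severity_fit.json"))
    utils::write.csv(studies, file.path(out, "studies_with_winter_temp.csv"),
                     row.names = FALSE)
    write_projection_maps(baseline,
                          csv_path = file.path(out, "maps_historical.csv"),
                          nc_path = file.path(out, "maps_historical.nc"))
    base_summary <- data.frame(
      scenario = "historical", target_year = baseline_spec$target_year,
      mean_temp = area_weighted_mean(baseline$mean_temp, baseline$lat),
      mean_prevalence = area_weighted_mean(baseline$prevalence, baseline$lat),
      mean_weekly_attacks = area_weighted_mean(baseline$weekly_attacks, baseline$lat),
      delta_mean_temp = 0, delta_prevalence = 0, delta_weekly_attacks = 0,
      stringsAsFactors = FALSE)
    summaries <- do.call(rbind, c(list(base_summary),
                                  lapply(scen_maps, `[[`, "summary")))
    rownames(summaries) <- NULL
    for (nm in names(scen_maps))
      write_projection_maps(scen_maps[[nm]],
                            csv_path = file.path(out, sprintf("maps_%s.csv", slug(nm))),
                            nc_path = file.path(out, sprintf("maps_%s.nc", slug(nm))))
    utils::write.csv(summaries, file.path(out, "summary.csv"), row.names = FALSE)
    log_lines <- c(
      sprintf("rpclim %s on R %s", as.character(utils::packageVersion("rpclim")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed: %s", seed),
      sprintf("config: %s", normalizePath(config_path)),
      "resolved parameters:",
      paste0("  ", strsplit(yaml::as.yaml(cfg), "\n")[[1]]))
    writeLines(log_lines, file.path(out, "run_log.txt"))
    summaries
  }) -> summaries

  invisible(list(prevalence_fit = prev_fit, severity_fit = sev_fit,
                 studies = studies, baseline = baseline,
                 scenarios = scen_maps, summary = summaries,
                 output_dir = out))
}
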