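#' Parameters for the synthetic climate generator
#'
#' The generator emulates the structure of bias-adjusted daily forcing files:
#' a latitudinal gradient, a seasonal cycle phased so the northern-hemisphere
#' minimum falls in mid-January (so the November-March window is the cold
#' season), independent daily Gaussian noise, a random land mask, and a
#' uniform warming offset per emission scenario. Defaults approximate
#' end-of-century warming relative to a ~2000 baseline under a
#' high-sensitivity earth-system model: +1.5 (RCP2.6), +2.5 (RCP4.5),
#' +3.0 (RCP6.0) and +4.5 degrees Celsius (RCP8.5).
#'
#' @param n_lat,n_lon grid shape; default 36 x 72 (5-degree resolution).
#' @param equator_temp annual-mean temperature at the equator, degC.
#' @param lat_gradient cooling per degree of absolute latitude, degC.
#' @param seasonal_amplitude half peak-to-trough seasonal swing, degC.
#' @param daily_noise_sd day-to-day Gaussian noise SD, degC.
#' @param scenario_offsets named vector of uniform warming per scenario, degC.
#' @param land_fraction probability a cell is land, in (0, 1].
#' @param seed integer seed; all generator randomness derives from it.
#' @return list of class `climate_sim_params`.
#' @export
climate_sim_params <- function(n_lat = 36L, n_lon = 72L,
                               equator_temp = 27, lat_gradient = 0.6,
                               seasonal_amplitude = 10, daily_noise_sd = 2,
                               scenario_offsets = c("RCP2.6" = 1.5, "RCP4.5" = 2.5,
                                                    "RCP6.0" = 3.0, "RCP8.5" = 4.5),
                               land_fraction = 0.3, seed = 1L) {
  if (daily_noise_sd < 0)
    rp_stop("rpclim_validation_error", "daily_noise_sd must be >= 0")
  if (land_fraction <= 0 || land_fraction > 1)
    rp_stop("rpclim_validation_error", "land_fraction must be in (0, 1]")
  structure(list(n_lat = n_lat, n_lon = n_lon, equator_temp = equator_temp,
                 lat_gradient = lat_gradient, seasonal_amplitude = seasonal_amplitude,
                 daily_noise_sd = daily_noise_sd, scenario_offsets = scenario_offsets,
                 land_fraction = land_fraction, seed = as.integer(seed)),
            class = "climate_sim_params")
}

#' Generate synthetic daily climate grids (historical + scenarios)
#'
#' Daily temperature at latitude `phi` on day-of-year `d`:
#' `equator_temp - lat_gradient * |phi| - seasonal_amplitude * cos(2*pi*(d - 15)/365.25) * sign(phi) + noise`,
#' so mid-January is the coldest time in the north and the warmest in the
#' south; each scenario grid is the historical field plus its uniform
#' offset. Reproducible: the same `(params, dates)` always yield the same
#' grids, and the land mask is shared across all five grids.
#'
#' @param params a [climate_sim_params()].
#' @param hist_dates,scen_dates daily `Date` axes for the historical and the
#'   scenario grids.
#' @param out_dir if non-`NULL`, the five grids are also written as NetCDF
#'   (variable `tasAdjust`, Kelvin) and the returned list carries a `paths`
#'   attribute.
#' @return named list of [temperature_grid()]: `historical` plus one per
#'   scenario offset.
#' @export
gen_climate <- function(params,
                        hist_dates = seq(as.Date("1998-01-01"), as.Date("1999-12-31"), "day"),
                        scen_dates = seq(as.Date("2098-01-01"), as.Date("2099-12-31"), "day"),
                        out_dir = NULL) {
  stopifnot(inherits(params, "climate_sim_params"))
  lat <- seq(-90 + 180 / params$n_lat / 2, 90 - 180 / params$n_lat / 2,
             length.out = params$n_lat)
  lon <- seq(-180 + 360 / params$n_lon / 2, 180 - 360 / params$n_lon / 2,
             length.out = params$n_lon)
  mask <- with_seed(derive_seed(params$seed, "climate"), {
    m <- matrix(stats::runif(params$n_lat * params$n_lon) < params$land_fraction,
                params$n_lat, params$n_lon)
    if (!any(m)) m[ceiling(params$n_lat / 2), 1L] <- TRUE
    m
  })
  # noise stream keyed by the date range: grids over the same days share
  # one weather realization, so a scenario differs from its baseline by
  # exactly the uniform offset
  base_values <- function(dates) {
    with_seed(derive_seed(params$seed, "climate") + as.integer(dates[1L]) %% 100003L, {
      doy <- as.integer(strftime(dates, "%j"))
      season <- -params$seasonal_amplitude *
        cos(2 * pi * (doy - 15) / 365.25)            # [time]
      latterm <- params$equator_temp - params$lat_gradient * abs(lat)  # [lat]
      v <- outer(season, sign(lat)) +
        matrix(latterm, length(dates), params$n_lat, byrow = TRUE)
      v <- array(rep(v, times = params$n_lon),
                 dim = c(length(dates), params$n_lat, params$n_lon))
      if (params$daily_noise_sd > 0)
        v <- v + array(stats::rnorm(length(v), 0, params$daily_noise_sd), dim = dim(v))
      dm <- dim(v)
      dim(v) <- c(dm[1L], dm[2L] * dm[3L])
      v[, !as.vector(mask)] <- NA_real_
      dim(v) <- dm
      v
    })
  }
  hist_v <- base_values(hist_dates)
  scen_v <- base_values(scen_dates)
  grids <- c(
    list(historical = temperature_grid(lat, lon, hist_dates, hist_v, source_units = "K")),
    lapply(as.list(params$scenario_offsets), function(off)
      temperature_grid(lat, lon, scen_dates, scen_v + off, source_units = "K")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    slug <- function(x) gsub("[^a-z0-9]+", "", tolower(x))
    paths <- vapply(names(grids), function(nm) {
      p <- file.path(out_dir, sprintf("tas_day_synthetic_%s.nc", slug(nm)))
      write_temperature_grid(grids[[nm]], p)
      p
    }, character(1))
    attr(grids, "paths") <- paths
  }
  grids
}

#' Parameters for the synthetic prevalence-survey generator
#'
#' Emulates the statistical structure of the extracted survey table: about
#' twenty mid-to-high-latitude sites whose prevalence follows a known linear
#' law in winter mean temperature, with survey noise, and sample sizes
#' spanning the extremes of the real table (67 to 4182 participants).
#'
#' @param true_slope prevalence change per degC (default -0.5).
#' @param true_intercept prevalence at 0 degC, percent; the default 6.5
#'   places the zero crossing at 13 degC, consistent with the no-attack
#'   temperature ceiling.
#' @param noise_sd survey noise SD, percentage points.
#' @param n_sites number of sites (>= 3).
#' @param latitude_range signed latitude band (degrees north) the sites are
#'   drawn from; the default 30-60 N mirrors the predominantly boreal survey
#'   table, keeping every site's November-March window in its cold season.
#' @param seed integer seed.
#' @export
study_sim_params <- function(true_slope = -0.5, true_intercept = 6.5, noise_sd = 1,
                             n_sites = 20L, latitude_range = c(30, 60), seed = 1L) {
  if (n_sites < 3L)
    rp_stop("rpclim_validation_error", "n_sites must be >= 3")
  structure(list(true_slope = true_slope, true_intercept = true_intercept,
                 noise_sd = noise_sd, n_sites = as.integer(n_sites),
                 latitude_range = latitude_range, seed = as.integer(seed)),
            class = "study_sim_params")
}

#' Generate a synthetic prevalence study table from a climate grid
#'
#' Places sites at random land cells within the latitude band, assigns each
#' the winter mean temperature of its own cell, and draws
#' `prevalence = clamp(intercept + slope * winter_temp + noise, 0, 100)`.
#' Sample sizes are log-uniform on [67, 4182].
#'
#' @param params a [study_sim_params()].
#' @param climate a [temperature_grid()] covering the winter ending in `year`.
#' @param year publication year assigned to every site; default the latest
#'   year whose winter window the grid fully covers.
#' @param window winter window, default [winter_window()].
#' @param out_path optional CSV path.
#' @return study table data frame (same schema as [read_study_table()]),
#'   with the generating `winter_temp` left unset (`NA`) so the pipeline's
#'   own linkage can be exercised; the true cell temperature is in
#'   `true_winter_temp`.
#' @export
gen_studies <- function(params, climate, year = NULL,
                        window = winter_window(), out_path = NULL) {
  stopifnot(inherits(params, "study_sim_params"), inherits(climate, "temperature_grid"))
  if (is.null(year)) {
    years <- as.integer(unique(format(climate$time, "%Y")))
    year <- max(Filter(function(y)
      all(window_dates(window, y) %in% climate$time), years))
  }
  field <- window_mean(climate, window, year)
  cells <- which(climate$land_mask, arr.ind = TRUE)
  slat <- climate$lat[cells[, 1L]]
  cells <- cells[slat >= params$latitude_range[1] & slat <= params$latitude_range[2], ,
                 drop = FALSE]
  if (nrow(cells) < params$n_sites)
    rp_stop("rpclim_placement_error",
            sprintf("only %d land cells in |lat| %g-%g for %d sites",
                    nrow(cells), params$latitude_range[1], params$latitude_range[2],
                    params$n_sites))
  with_seed(derive_seed(params$seed, "studies"), {
    pick <- cells[sample.int(nrow(cells), params$n_sites), , drop = FALSE]
    wt <- field$values[pick]
    prev <- pmin(pmax(params$true_intercept + params$true_slope * wt +
                        stats::rnorm(params$n_sites, 0, params$noise_sd), 0), 100)
    n <- round(exp(stats::runif(params$n_sites, log(67), log(4182))))
  })
  df <- data.frame(
    study = sprintf("SYN%02d", seq_len(params$n_sites)),
    year = year,
    country = "Synthetica",
    city = sprintf("site%02d", seq_len(params$n_sites)),
    latitude = climate$lat[pick[, 1L]],
    longitude = climate$lon[pick[, 2L]],
    sample_size = n,
    prevalence = prev,
    winter_temp = NA_real_,
    true_winter_temp = wt,
    stringsAsFactors = FALSE)
  if (!is.null(out_path))
    utils::write.csv(df, out_path, row.names = FALSE)
  df
}

#' Parameters for the synthetic attack-diary generator
#'
#' Emulates a pooled series of n-of-1 daily diaries: several patients, each
#' contributing hundreds of days (the defaults give 2200 patient-days,
#' matching the scale of a deposited trial series of over 2000 days), daily
#' temperature uniform over a cool-season range, and counts Poisson with
#' log-rate linear in temperature.
#'
#' @param true_coefficients named log-rate-scale coefficients; must include
#'   `"(Intercept)"`, other names are covariates (default temperature slope
#'   -0.12 per degC).
#' @param n_patients,n_days patients and days per patient.
#' @param temperature_range degC interval the daily temperatures are drawn from.
#' @param seed integer seed.
#' @export
diary_sim_params <- function(true_coefficients = c("(Intercept)" = 0.3,
                                                   temperature = -0.12),
                             n_patients = 4L, n_days = 550L,
                             temperature_range = c(-5, 15), seed = 1L) {
  if (n_patients * n_days < 10L)
    rp_stop("rpclim_validation_error", "need n_patients * n_days >= 10")
  if (!"(Intercept)" %in% names(true_coefficients))
    rp_stop("rpclim_validation_error", "true_coefficients must include '(Intercept)'")
  structure(list(true_coefficients = true_coefficients,
                 n_patients = as.integer(n_patients), n_days = as.integer(n_days),
                 temperature_range = temperature_range, seed = as.integer(seed)),
            class = "diary_sim_params")
}

#' Generate synthetic daily attack diaries
#'
#' @param params a [diary_sim_params()].
#' @param out_path optional CSV path.
#' @return diary data frame (`patient_id, day, attack_count, temperature`).
#' @export
gen_diaries <- function(params, out_path = NULL) {
  stopifnot(inherits(params, "diary_sim_params"))
  n <- params$n_patients * params$n_days
  with_seed(derive_seed(params$seed, "diaries"), {
    temp <- stats::runif(n, params$temperature_range[1], params$temperature_range[2])
    b <- params$true_coefficients
    eta <- b[["(Intercept)"]] + b[["temperature"]] * temp
    counts <- stats::rpois(n, exp(eta))
  })
  df <- data.frame(
    patient_id = rep(sprintf("P%02d", seq_len(params$n_patients)),
                     each = params$n_days),
    day = rep(seq(as.Date("1999-01-01"), by = "day", length.out = params$n_days),
              times = params$n_patients),
    attack_count = counts,
    temperature = temp,
    stringsAsFactors = FALSE)
  if (!is.null(out_path))
    utils::write.csv(df, out_path, row.names = FALSE)
  df
}
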