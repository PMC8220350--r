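#' Read a prevalence study table
#'
#' Reads a CSV of population prevalence surveys in the schema of the
#' systematic-review extraction table bundled with the package
#' (`system.file("extdata", "study_table.csv", package = "rpclim")`):
#' columns `study, year, country, city, latitude, sample_size, prevalence`
#' with optional `longitude` and `mean_age`. Missing longitudes are filled
#' from the bundled city gazetteer; an explicit longitude column overrides it.
#'
#' @param path CSV file path.
#' @param gazetteer optional data frame `city, country, lat, lon`; defaults to
#'   the bundled gazetteer.
#' @return data frame of study records with a `winter_temp` column
#'   (`NA` until assigned by [assign_winter_temps()]).
#' @export
read_study_table <- function(path, gazetteer = NULL) {
  if (!file.exists(path))
    rp_stop("rpclim_io_error", sprintf("study table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study", "year", "country", "city", "latitude", "sample_size", "prevalence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    rp_stop("rpclim_validation_error",
            sprintf("study table missing column(s): %s", paste(miss, collapse = ", ")))
  bad <- which(is.na(df$prevalence) | df$prevalence < 0 | df$prevalence > 100)
  if (length(bad))
    rp_stop("rpclim_validation_error",
            sprintf("prevalence outside [0, 100] in row(s) %s (study %s)",
                    paste(bad, collapse = ", "),
                    paste(df$study[bad], collapse = ", ")))
  bad <- which(is.na(df$sample_size) | df$sample_size < 1)
  if (length(bad))
    rp_stop("rpclim_validation_error",
            sprintf("sample_size < 1 in row(s) %s", paste(bad, collapse = ", ")))
  bad <- which(is.na(df$latitude) | abs(df$latitude) > 90)
  if (length(bad))
    rp_stop("rpclim_validation_error",
            sprintf("latitude outside [-90, 90] in row(s) %s", paste(bad, collapse = ", ")))

  if (is.null(gazetteer)) gazetteer <- rpclim_gazetteer()
  if (!"longitude" %in% names(df)) df$longitude <- NA_real_
  fill <- which(is.na(df$longitude))
  if (length(fill)) {
    hit <- match(tolower(df$city[fill]), tolower(gazetteer$city))
    unknown <- fill[is.na(hit)]
    if (length(unknown))
      rp_stop("rpclim_linkage_error",
              sprintf("no longitude and city not in gazetteer: %s",
                      paste(unique(df$city[unknown]), collapse = ", ")))
    df$longitude[fill] <- gazetteer$lon[hit]
  }
  if (!"winter_temp" %in% names(df)) df$winter_temp <- NA_real_
  df
}

#' @rdname read_study_table
#' @export
rpclim_gazetteer <- function() {
  utils::read.csv(system.file("extdata", "gazetteer.csv", package = "rpclim"),
                  stringsAsFactors = FALSE)
}

#' Assign each study its preceding-winter mean temperature
#'
#' For a study published in year `Y`, the exposure is the cold-season mean
#' ending in `Y` (by default 1 Nov `Y-1` to 31 Mar `Y`), evaluated at the
#' grid cell nearest the study city. Southern-hemisphere sites can be given
#' the mirrored May-September window via `south_window`.
#'
#' @param records study table from [read_study_table()].
#' @param grid a [temperature_grid()] covering every study's window.
#' @param window averaging window, default [winter_window()].
#' @param south_window optional [calendar_window()] used for records with
#'   `latitude < 0` (e.g. [austral_winter_window()]); default `NULL` applies
#'   `window` everywhere.
#' @param max_radius ring search radius for the nearest-cell extraction.
#' @return `records` with `winter_temp` filled, in degrees Celsius.
#' @export
assign_winter_temps <- function(records, grid, window = winter_window(),
                                south_window = NULL, max_radius = 3L) {
  stopifnot(inherits(grid, "temperature_grid"))
  fields <- list()  # cache one field per (window key, year)
  for (i in seq_len(nrow(records))) {
    w <- if (!is.null(south_window) && records$latitude[i] < 0) south_window else window
    key <- sprintf("%02d%02d-%02d%02d-%d", w$start_month, w$start_day,
                   w$end_month, w$end_day, records$year[i])
    if (is.null(fields[[key]])) {
      fields[[key]] <- withCallingHandlers(
        window_mean(grid, w, records$year[i]),
        rpclim_error = function(e) {
          e$message <- sprintf("study '%s' (%s %d): %s", records$study[i],
                               records$city[i], records$year[i], conditionMessage(e))
          stop(e)
        })
    }
    records$winter_temp[i] <- tryCatch(
      as.numeric(extract_at(fields[[key]], records$latitude[i],
                            records$longitude[i], max_radius = max_radius)),
      rpclim_no_land_cell = function(e)
        rp_stop("rpclim_no_land_cell",
                sprintf("study '%s' (%s): %s", records$study[i],
                        records$city[i], conditionMessage(e))))
  }
  records
}

#' Fit the linear prevalence-temperature model
#'
#' Ordinary (or sample-size-weighted) least squares of survey prevalence
#' (percent) on winter mean temperature (degrees Celsius). The slope is the
#' expected change in population prevalence per degree of warming; its
#' negative zero crossing `-intercept/slope` is the temperature above which
#' the model predicts no Raynaud's phenomenon.
#'
#' @param records study table with `winter_temp` assigned (or, for
#'   `predictor = "abs_latitude"`, any table with `latitude`).
#' @param weighting `"none"` (default) or `"sample_size"`.
#' @param predictor `"winter_temp"` (default) or `"abs_latitude"`, a
#'   latitude-only fallback for sensitivity analysis when no climate data
#'   is linked.
#' @return object of class `prevalence_fit`: `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `residual_sd`, `n_records`,
#'   `p_value_slope`, `weighting`, `predictor`.
#' @export
fit_prevalence <- function(records, weighting = c("none", "sample_size"),
                           predictor = c("winter_temp", "abs_latitude")) {
  weighting <- match.arg(weighting)
  predictor <- match.arg(predictor)
  x <- switch(predictor,
              winter_temp = records$winter_temp,
              abs_latitude = abs(records$latitude))
  y <- records$prevalence
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L)
    rp_stop("rpclim_degenerate_design",
            "all predictor values identical; slope is not identifiable")
  w <- if (weighting == "sample_size") records$sample_size[ok] else NULL
  fm <- stats::lm(y ~ x, weights = w)
  # collinear calibration data are legitimate here; the residual SD reports it
  sm <- withCallingHandlers(
    summary(fm),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- sm$coefficients
  structure(
    list(slope = unname(co["x", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         slope_se = unname(co["x", "Std. Error"]),
         intercept_se = unname(co["(Intercept)", "Std. Error"]),
         residual_sd = sm$sigma,
         n_records = length(y),
         p_value_slope = if (fm$df.residual > 0) unname(co["x", "Pr(>|t|)"]) else NA_real_,
         weighting = weighting,
         predictor = predictor),
    class = "prevalence_fit")
}

#' @export
print.prevalence_fit <- function(x, ...) {
  cat(sprintf("<prevalence_fit> prevalence = %.4f %+.4f * %s  (n = %d)\n",
              x$intercept, x$slope, x$predictor, x$n_records))
  cat(sprintf("  slope SE %.4f, p = %.3g; residual SD %.3f%%\n",
              x$slope_se, x$p_value_slope, x$residual_sd))
  if (!is.na(x$slope) && x$slope < 0)
    cat(sprintf("  zero crossing at %.2f degC\n", zero_crossing(x)))
  invisible(x)
}

#' Predict population prevalence at a temperature
#'
#' Linear prediction clamped to the physical range 0-100 percent; regions
#' warmer than the zero crossing are predicted free of Raynaud's phenomenon.
#'
#' @param fit a [fit_prevalence()] result.
#' @param temperature degrees Celsius (vector or matrix; `NA` passes through).
#' @return prevalence percent, same shape as `temperature`.
#' @export
predict_prevalence <- function(fit, temperature) {
  stopifnot(inherits(fit, "prevalence_fit"))
  p <- fit$intercept + fit$slope * temperature
  p[] <- pmin(pmax(p, 0), 100)
  p
}

#' Temperature at which predicted prevalence reaches zero
#'
#' @param fit a [fit_prevalence()] result with negative slope.
#' @return temperature in degrees Celsius.
#' @export
zero_crossing <- function(fit) {
  stopifnot(inherits(fit, "prevalence_fit"))
  if (!is.finite(fit$slope) || fit$slope >= 0)
    rp_stop("rpclim_no_crossing",
            sprintf("slope is %.4g >= 0: predicted prevalence never reaches zero", fit$slope))
  -fit$intercept / fit$slope
}

#' Serialize / read a prevalence fit as JSON
#' @param fit a `prevalence_fit`.
#' @param path JSON path.
#' @export
write_prevalence_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prevalence_fit
#' @export
read_prevalence_fit <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE), class = "prevalence_fit")
}
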