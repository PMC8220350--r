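#' Gridded daily near-surface temperature
#'
#' In-memory container for a daily temperature grid in degrees Celsius,
#' the shape the bias-adjusted ISIMIP forcing files (variable `tasAdjust`)
#' take after loading. Values are stored as a `[time, lat, lon]` array with
#' `NA` over permanently-missing (ocean) cells; the land mask is derived as
#' "has at least one non-missing time step".
#'
#' @param lat latitude cell centers, degrees north (stored as given).
#' @param lon longitude cell centers, degrees east.
#' @param time daily `Date` axis, strictly increasing, no gaps or duplicates.
#' @param values numeric array, dim `c(length(time), length(lat), length(lon))`,
#'   in degrees Celsius; `NA` marks missing cells.
#' @param source_units units string of the variable as found on disk.
#' @param variable variable name the grid was read from.
#' @return object of class `temperature_grid`.
#' @export
temperature_grid <- function(lat, lon, time, values,
                             source_units = "degC", variable = "tasAdjust") {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  time <- as.Date(time)
  if (!is.array(values) || length(dim(values)) != 3L ||
      !all(dim(values) == c(length(time), length(lat), length(lon))))
    rp_stop("rpclim_shape_error",
            "values must be a [time, lat, lon] array matching the axes")
  if (length(time) > 1L) {
    dt <- diff(as.integer(time))
    if (any(dt != 1L))
      rp_stop("rpclim_calendar_error",
              "time axis must be strictly increasing with daily steps and no duplicates")
  }
  finite <- values[!is.na(values)]
  if (length(finite) && (min(finite) < -90 || max(finite) > 60))
    rp_stop("rpclim_units_error",
            sprintf("temperatures outside [-90, 60] degC after conversion (range %.1f..%.1f); wrong units?",
                    min(finite), max(finite)))
  land_mask <- apply(!is.na(values), c(2L, 3L), any)
  structure(
    list(lat = lat, lon = lon, time = time, values = values,
         land_mask = land_mask, source_units = source_units, variable = variable),
    class = "temperature_grid")
}

#' @export
print.temperature_grid <- function(x, ...) {
  cat(sprintf("<temperature_grid> %d x %d cells, %d days (%s .. %s), %d land cells\n",
              length(x$lat), length(x$lon), length(x$time),
              format(min(x$time)), format(max(x$time)), sum(x$land_mask)))
  invisible(x)
}

is_kelvin_units <- function(u) tolower(u) %in% c("k", "kelvin", "degk", "degrees_k")
is_celsius_units <- function(u)
  tolower(u) %in% c("degc", "c", "celsius", "degrees_c", "degree_celsius", "deg_c", "°c")

parse_time_units <- function(units, vals) {
  m <- regmatches(units,
                  regexec("^days since ([0-9]{1,4})-([0-9]{1,2})-([0-9]{1,2})", units))[[1]]
  if (length(m) != 4L)
    rp_stop("rpclim_calendar_error",
            sprintf("unsupported time units '%s' (only daily 'days since YYYY-MM-DD' axes)", units))
  origin <- as.Date(sprintf("%04d-%02d-%02d",
                            as.integer(m[2]), as.integer(m[3]), as.integer(m[4])))
  # ISIMIP daily files time-stamp at noon (offsets x.5); truncate to the day
  origin + floor(as.numeric(vals) + 1e-6)
}

#' Read a CF-convention gridded daily temperature file
#'
#' Reads a NetCDF file with a `(time, lat, lon)` temperature variable such as
#' the ISIMIP `tasAdjust` files, converts Kelvin to degrees Celsius at load,
#' truncates the daily time axis to calendar dates, and derives the land mask
#' from the variable's fill value.
#'
#' @param path NetCDF file path.
#' @param variable_name variable to read; default `"tasAdjust"`.
#' @return a [temperature_grid()].
#' @export
read_temperature_grid <- function(path, variable_name = "tasAdjust") {
  if (!file.exists(path))
    rp_stop("rpclim_io_error", sprintf("climate file not found: %s", path))
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable_name %in% names(nc$var))
    rp_stop("rpclim_var_not_found",
            sprintf("variable '%s' not found in %s (has: %s)",
                    variable_name, path, paste(names(nc$var), collapse = ", ")))
  var <- nc$var[[variable_name]]
  dn <- vapply(var$dim, function(d) d$name, character(1))
  i_lon <- match_dim(dn, c("lon", "longitude"))
  i_lat <- match_dim(dn, c("lat", "latitude"))
  i_time <- match_dim(dn, c("time"))
  lon <- var$dim[[i_lon]]$vals
  lat <- var$dim[[i_lat]]$vals
  tdim <- var$dim[[i_time]]
  dates <- parse_time_units(tdim$units, tdim$vals)
  if (anyDuplicated(dates) || (length(dates) > 1 && any(diff(as.integer(dates)) != 1L)))
    rp_stop("rpclim_calendar_error",
            sprintf("time axis of %s is not a daily calendar axis", path))

  raw <- ncdf4::ncvar_get(nc, variable_name, collapse_degen = FALSE)
  # ncvar_get returns dims in file order with the fastest-varying first
  perm <- match(c(i_time, i_lat, i_lon), seq_along(dn))
  vals <- aperm(raw, perm)

  units <- var$units %||% ""
  if (is_kelvin_units(units)) {
    vals <- vals - 273.15
  } else if (!is_celsius_units(units)) {
    rp_stop("rpclim_units_error",
            sprintf("unsupported temperature units '%s' in %s", units, path))
  }
  temperature_grid(lat = lat, lon = lon, time = dates, values = vals,
                   source_units = units, variable = variable_name)
}

match_dim <- function(names, candidates) {
  i <- which(tolower(names) %in% candidates)
  if (length(i) != 1L)
    rp_stop("rpclim_io_error",
            sprintf("expected exactly one of dims {%s}, found in (%s)",
                    paste(candidates, collapse = ","), paste(names, collapse = ",")))
  i
}

#' Write a temperature grid as CF NetCDF
#'
#' Writes the grid with dimensions `(time, lat, lon)`, time as
#' `days since 1661-01-01`, values in Kelvin (the ISIMIP convention) and
#' fill value `1e20` over masked cells. Round-trips through
#' [read_temperature_grid()].
#'
#' @param grid a [temperature_grid()].
#' @param path output path.
#' @param variable_name NetCDF variable name.
#' @return `path`, invisibly.
#' @export
write_temperature_grid <- function(grid, path, variable_name = grid$variable) {
  stopifnot(inherits(grid, "temperature_grid"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  dtim <- ncdf4::ncdim_def("time", "days since 1661-01-01",
                           as.numeric(grid$time - as.Date("1661-01-01")),
                           calendar = "standard")
  v <- ncdf4::ncvar_def(variable_name, "K", list(dlon, dlat, dtim),
                        missval = 1e20, prec = "double")
  nc <- ncdf4::nc_create(path, list(v))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, aperm(grid$values + 273.15, c(3L, 2L, 1L)))
  invisible(path)
}

#' Mean temperature field over a calendar window
#'
#' Per-cell arithmetic mean over exactly the days of `window` ending in
#' `end_year` (e.g. the winter window ending 31 March `end_year`, or the
#' Christmas week of `end_year`). Masked cells stay masked.
#'
#' @param grid a [temperature_grid()].
#' @param window a [calendar_window()].
#' @param end_year calendar year the window ends in.
#' @return object of class `temperature_field`: lat/lon axes plus a
#'   `[lat, lon]` matrix of mean temperature in degrees Celsius (`NA` where
#'   masked), with the day count in `$n_days`.
#' @export
window_mean <- function(grid, window, end_year) {
  stopifnot(inherits(grid, "temperature_grid"))
  dates <- window_dates(window, end_year)
  idx <- match(dates, grid$time)
  if (anyNA(idx)) {
    missing <- dates[is.na(idx)]
    rp_stop("rpclim_coverage_error",
            sprintf("grid does not cover %d window day(s): %s%s",
                    length(missing), paste(utils::head(missing, 10L), collapse = ", "),
                    if (length(missing) > 10L) ", ..." else ""),
            missing_dates = missing)
  }
  m <- colMeans(grid$values[idx, , , drop = FALSE], dims = 1L)
  m[!grid$land_mask] <- NA_real_
  temperature_field(grid$lat, grid$lon, m,
                    window = window, end_year = end_year, n_days = length(dates))
}

#' 2D temperature (or derived) field on a grid
#'
#' @param lat,lon cell-center axes (degrees).
#' @param values `[lat, lon]` numeric matrix; `NA` marks masked cells.
#' @param ... extra metadata fields (window, end_year, ...).
#' @return object of class `temperature_field`.
#' @export
temperature_field <- function(lat, lon, values, ...) {
  if (!is.matrix(values) || !all(dim(values) == c(length(lat), length(lon))))
    rp_stop("rpclim_shape_error", "values must be a [lat, lon] matrix matching the axes")
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 values = values, ...),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("<temperature_field> %d x %d, %d unmasked, range %s\n",
              length(x$lat), length(x$lon), sum(!is.na(x$values)),
              if (all(is.na(x$values))) "all NA"
              else sprintf("%.2f .. %.2f", min(x$values, na.rm = TRUE),
                           max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Extract the field value nearest to a point
#'
#' Returns the value of the nearest unmasked cell center by great-circle
#' distance, the gridded analogue of "the nearest weather station". The
#' search widens ring by ring around the enclosing cell up to `max_radius`
#' rings, which keeps coastal cities from falling onto masked sea cells of
#' land-only files. Distance ties are broken towards the cell with smaller
#' absolute latitude, then smaller longitude.
#'
#' @param field a [temperature_field()].
#' @param latitude,longitude query point, degrees.
#' @param max_radius maximum search radius in grid cells (rings).
#' @return the field value at the selected cell (scalar), with the chosen
#'   cell's coordinates attached as attributes `lat`/`lon`.
#' @export
extract_at <- function(field, latitude, longitude, max_radius = 3L) {
  stopifnot(inherits(field, "temperature_field"))
  if (!any(!is.na(field$values)))
    rp_stop("rpclim_no_land_cell", "field has no unmasked cell")
  nlat <- length(field$lat); nlon <- length(field$lon)
  i0 <- which.min(abs(field$lat - latitude))
  dl <- abs(((field$lon - longitude + 180) %% 360) - 180)
  j0 <- which.min(dl)

  # does the lon axis wrap the globe?
  span <- diff(range(field$lon))
  step <- if (nlon > 1L) span / (nlon - 1L) else 360
  wraps <- (span + step) >= 359

  is_cand <- matrix(FALSE, nlat, nlon)
  for (r in 0:max_radius) {
    ii <- (i0 - r):(i0 + r)
    ii <- ii[ii >= 1L & ii <= nlat]
    jj <- (j0 - r):(j0 + r)
    jj <- if (wraps) unique((jj - 1L) %% nlon + 1L) else jj[jj >= 1L & jj <= nlon]
    is_cand[ii, jj] <- TRUE
  }
  cand <- which(is_cand & !is.na(field$values), arr.ind = TRUE)
  if (nrow(cand) == 0L)
    rp_stop("rpclim_no_land_cell",
            sprintf("no unmasked cell within %d ring(s) of (%.2f, %.2f)",
                    max_radius, latitude, longitude))
  clat <- field$lat[cand[, 1L]]
  clon <- field$lon[cand[, 2L]]
  d <- geosphere::distHaversine(cbind(longitude, latitude), cbind(clon, clat))
  d <- round(d)  # metre resolution; exposes genuine geometric ties
  pick <- order(d, abs(clat), clon)[1L]
  out <- field$values[cand[pick, 1L], cand[pick, 2L]]
  attr(out, "lat") <- clat[pick]
  attr(out, "lon") <- clon[pick]
  out
}

#' Write a 2D field as CSV (lat, lon, value)
#'
#' @param field a [temperature_field()].
#' @param path output CSV path.
#' @param value_name column name for the values.
#' @export
write_field_csv <- function(field, path, value_name = "value") {
  df <- data.frame(lat = rep(field$lat, times = length(field$lon)),
                   lon = rep(field$lon, each = length(field$lat)),
                   value = as.vector(field$values))
  names(df)[3L] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
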