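#' Calendar averaging window
#'
#' Defines a recurring month/day window, such as the boreal cold season
#' (1 November to 31 March) used to characterise each survey site's winter
#' exposure, or the Christmas week used for the projection maps. A window
#' whose start falls after its end spans the year boundary: the window
#' "ending in" year `Y` then starts in year `Y - 1`.
#'
#' @param start start of the window, `"MM-DD"` string.
#' @param end end of the window (inclusive), `"MM-DD"` string.
#' @return An object of class `calendar_window` with fields `start_month`,
#'   `start_day`, `end_month`, `end_day` and the derived flag
#'   `spans_year_boundary`.
#' @examples
#' winter_window()          # Nov 1 -> Mar 31, spans the year boundary
#' calendar_window("12-22", "12-28")  # Christmas week
#' @export
calendar_window <- function(start = "11-01", end = "03-31") {
  parse_md <- function(x) {
    m <- regmatches(x, regexec("^([0-9]{1,2})-([0-9]{1,2})$", x))[[1]]
    if (length(m) != 3L)
      rp_stop("rpclim_calendar_error", sprintf("invalid month-day '%s' (want 'MM-DD')", x))
    md <- as.integer(m[2:3])
    if (md[1] < 1L || md[1] > 12L || md[2] < 1L || md[2] > 31L)
      rp_stop("rpclim_calendar_error", sprintf("month-day '%s' out of range", x))
    md
  }
  s <- parse_md(start)
  e <- parse_md(end)
  structure(
    list(start_month = s[1], start_day = s[2],
         end_month = e[1], end_day = e[2],
         spans_year_boundary = (s[1] > e[1]) || (s[1] == e[1] && s[2] > e[2])),
    class = "calendar_window")
}

#' @rdname calendar_window
#' @export
winter_window <- function() calendar_window("11-01", "03-31")

#' @rdname calendar_window
#' @details `austral_winter_window()` is the southern-hemisphere mirror
#'   (1 May to 30 September) offered for sites south of the equator.
#' @export
austral_winter_window <- function() calendar_window("05-01", "09-30")

#' @rdname calendar_window
#' @export
christmas_window <- function() calendar_window("12-22", "12-28")

#' Enumerate the calendar dates of a window ending in a given year
#'
#' For a boundary-spanning window such as Nov 1 -> Mar 31, `end_year = 1999`
#' yields 1 Nov 1998 through 31 Mar 1999 (151 days; 152 when February of the
#' end year has 29 days).
#'
#' @param window a [calendar_window()].
#' @param end_year calendar year in which the window ends.
#' @return vector of `Date`, strictly increasing, daily.
#' @export
window_dates <- function(window, end_year) {
  stopifnot(inherits(window, "calendar_window"))
  start_year <- if (window$spans_year_boundary) end_year - 1L else end_year
  from <- as.Date(sprintf("%04d-%02d-%02d", start_year, window$start_month, window$start_day))
  to <- as.Date(sprintf("%04d-%02d-%02d", end_year, window$end_month, window$end_day))
  if (is.na(from) || is.na(to))
    rp_stop("rpclim_calendar_error",
            sprintf("window %02d-%02d -> %02d-%02d has no valid dates in year %d",
                    window$start_month, window$start_day,
                    window$end_month, window$end_day, end_year))
  seq(from, to, by = "day")
}

#' @export
print.calendar_window <- function(x, ...) {
  cat(sprintf("<calendar_window> %02d-%02d -> %02d-%02d%s\n",
              x$start_month, x$start_day, x$end_month, x$end_day,
              if (x$spans_year_boundary) " (spans year boundary)" else ""))
  invisible(x)
}
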