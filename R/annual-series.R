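# Year-indexed global scalar series: the carrier for every time-resolved
# quantity in the package (emissions, fluxes, concentrations, forcings).

#' Annual global time series
#'
#' An `annual_series` is a contiguous, year-indexed vector of global annual
#' means with a unit tag.  It is the universal currency of the package:
#' emission and flux series, concentration trajectories and forcing series
#' are all carried in this container.
#'
#' @param start_year First calendar year of the series.
#' @param values Numeric vector of annual values, one per year, all finite.
#' @param units Unit string, e.g. `"TgN yr-1"`, `"PgC yr-1"`, `"ppmv"`,
#'   `"ppbv"`, `"ppb"`, `"W m-2"`, `"K"` or `"1"` (dimensionless).
#'
#' @return An object of class `annual_series`.
#' @examples
#' x <- annual_series(2015, c(1, 2, 3), "TgN yr-1")
#' series_years(x)
#' series_mean(x, 2015, 2016)
#' @export
annual_series <- function(start_year, values, units) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("an annual_series needs at least one value", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all annual_series values must be finite", call. = FALSE)
  if (!is.character(units) || length(units) != 1L || !nzchar(units))
    stop("units must be a single non-empty string", call. = FALSE)
  start_year <- as.integer(start_year)
  if (is.na(start_year))
    stop("start_year must be an integer calendar year", call. = FALSE)
  structure(
    list(start_year = start_year, values = values, units = units),
    class = "annual_series"
  )
}

#' @rdname annual_series
#' @param x An object.
#' @export
is_annual_series <- function(x) inherits(x, "annual_series")

#' Year axis of an annual series
#'
#' @param x An [annual_series()].
#' @return Integer vector of calendar years.
#' @export
series_years <- function(x) {
  stopifnot(is_annual_series(x))
  seq(x$start_year, length.out = length(x$values))
}

#' Value of an annual series in a given year
#'
#' @param x An [annual_series()].
#' @param year Calendar year; must lie on the series axis.
#' @return A single numeric value.
#' @export
series_value <- function(x, year) {
  yrs <- series_years(x)
  i <- match(as.integer(year), yrs)
  if (is.na(i))
    stop(sprintf("year %d is outside the series axis %d-%d",
                 as.integer(year), yrs[1L], yrs[length(yrs)]), call. = FALSE)
  x$values[i]
}

#' Subset an annual series to an inclusive year window
#'
#' @param x An [annual_series()].
#' @param from,to First and last calendar year of the window.
#' @return An [annual_series()] covering `from:to`.
#' @export
series_window <- function(x, from, to) {
  yrs <- series_years(x)
  from <- as.integer(from); to <- as.integer(to)
  if (from > to) stop("'from' must not exceed 'to'", call. = FALSE)
  if (from < yrs[1L] || to > yrs[length(yrs)])
    stop(sprintf("window %d-%d outside the series axis %d-%d",
                 from, to, yrs[1L], yrs[length(yrs)]), call. = FALSE)
  annual_series(from, x$values[match(from, yrs):match(to, yrs)], x$units)
}

#' Mean of an annual series over an inclusive year window
#'
#' @inheritParams series_window
#' @return A single numeric value.
#' @export
series_mean <- function(x, from, to) {
  mean(series_window(x, from, to)$values)
}

same_axis <- function(a, b) {
  a$start_year == b$start_year && length(a$values) == length(b$values)
}

check_same_axis <- function(a, b, what = "series") {
  if (!same_axis(a, b))
    stop(sprintf("mismatched year axes between %s (%d..%d vs %d..%d)", what,
                 a$start_year, a$start_year + length(a$values) - 1L,
                 b$start_year, b$start_year + length(b$values) - 1L),
         call. = FALSE)
  invisible(TRUE)
}

check_units <- function(x, units, what = "series") {
  if (!identical(x$units, units))
    stop(sprintf("%s must have units '%s', got '%s'", what, units, x$units),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
Ops.annual_series <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-")
      return(annual_series(e1$start_year, -e1$values, e1$units))
    if (.Generic == "+") return(e1)
    stop("unsupported unary operation on annual_series", call. = FALSE)
  }
  both <- is_annual_series(e1) && is_annual_series(e2)
  if (both) {
    check_same_axis(e1, e2)
    if (.Generic %in% c("+", "-")) {
      if (!identical(e1$units, e2$units))
        stop(sprintf("cannot %s series with units '%s' and '%s'",
                     if (.Generic == "+") "add" else "subtract",
                     e1$units, e2$units), call. = FALSE)
      return(annual_series(e1$start_year,
                           get(.Generic)(e1$values, e2$values), e1$units))
    }
    if (.Generic %in% c("*", "/"))
      return(annual_series(e1$start_year,
                           get(.Generic)(e1$values, e2$values), e1$units))
    stop(sprintf("operation '%s' not defined for annual_series", .Generic),
         call. = FALSE)
  }
  # series op scalar (units retained; scalar taken as dimensionless)
  s <- if (is_annual_series(e1)) e1 else e2
  k <- if (is_annual_series(e1)) e2 else e1
  if (!is.numeric(k)) stop("annual_series arithmetic needs numeric operands",
                           call. = FALSE)
  v <- if (is_annual_series(e1)) get(.Generic)(e1$values, k)
       else get(.Generic)(k, e2$values)
  annual_series(s$start_year, v, s$units)
}

#' Sum a list of annual series sharing one axis and unit
#'
#' @param series_list List of [annual_series()] objects.
#' @return An [annual_series()] with the elementwise sum.
#' @export
series_sum <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  out <- series_list[[1L]]
  if (length(series_list) > 1L)
    for (s in series_list[-1L]) out <- out + s
  out
}

#' Running (cumulative) sum of an annual series
#'
#' @param x An [annual_series()].
#' @return An [annual_series()] whose value in year y is the sum over
#'   `start_year..y`.
#' @export
series_cumsum <- function(x) {
  annual_series(x$start_year, cumsum(x$values), x$units)
}

#' @export
print.annual_series <- function(x, ...) {
  yrs <- series_years(x)
  cat(sprintf("<annual_series> %d-%d [%s]\n", yrs[1L], yrs[length(yrs)],
              x$units))
  print(utils::head(stats::setNames(x$values, yrs), 10L))
  if (length(x$values) > 10L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = series_years(x), value = x$values, units = x$units,
             stringsAsFactors = FALSE)
}
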