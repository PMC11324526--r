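# Tidy-CSV readers/writers for every container, plus the JSON report
# writer.  All dialects round-trip losslessly; readers validate units and
# year contiguity and name any gap.

check_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("'%s' lacks required columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

check_contiguous <- function(years, what) {
  years <- sort(unique(as.integer(years)))
  full <- seq(years[1L], years[length(years)])
  gap <- setdiff(full, years)
  if (length(gap))
    stop(sprintf("non-contiguous years in %s; missing: %s", what,
                 paste(gap, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Write / read an annual series as tidy CSV
#'
#' Columns `year`, `value`, `units`.  Reading validates that a units column
#' is present and non-empty and that the year axis is contiguous (any gap
#' is reported by year).
#'
#' @param x An [annual_series()].
#' @param path File path.
#' @return `write_series_csv()` returns `path` invisibly;
#'   `read_series_csv()` returns an [annual_series()].
#' @export
write_series_csv <- function(x, path) {
  stopifnot(is_annual_series(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("year", "value", "units"), path)
  units <- unique(df$units)
  if (length(units) != 1L || is.na(units) || !nzchar(units))
    stop(sprintf("'%s' must carry one non-empty units tag", path),
         call. = FALSE)
  df <- df[order(df$year), ]
  check_contiguous(df$year, path)
  annual_series(df$year[1L], df$value, units)
}

#' Write / read a sectoral inventory as tidy CSV
#'
#' Long format with columns `year`, `species`, `sector`, `value`, `units`.
#'
#' @param inventory Inventory data frame (see [generate_inventory()]).
#' @param path File path.
#' @return `write_inventory_csv()` returns `path` invisibly;
#'   `read_inventory_csv()` returns the inventory data frame.
#' @export
write_inventory_csv <- function(inventory, path) {
  check_columns(inventory, c("year", "species", "sector", "value", "units"),
                "inventory")
  utils::write.csv(inventory, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_inventory_csv
#' @export
read_inventory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("year", "species", "sector", "value", "units"), path)
  if (any(is.na(df$units) | !nzchar(df$units)))
    stop(sprintf("'%s' has unit-less rows", path), call. = FALSE)
  for (sp in unique(df$species))
    check_contiguous(df$year[df$species == sp],
                     sprintf("%s (species %s)", path, sp))
  df
}

#' Write / read forcing components as CSV
#'
#' Columns `agent`, `central`, `low`, `high` (W m-2).
#'
#' @param components A `forcing_components` data frame.
#' @param path File path.
#' @return `write_components_csv()` returns `path` invisibly;
#'   `read_components_csv()` returns a `forcing_components` data frame.
#' @export
write_components_csv <- function(components, path) {
  check_columns(components, c("agent", "central", "low", "high"),
                "components")
  utils::write.csv(as.data.frame(components), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_components_csv
#' @export
read_components_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("agent", "central", "low", "high"), path)
  do.call(forcing_components,
          lapply(seq_len(nrow(df)), function(i)
            forcing_component(df$agent[i], df$central[i], df$low[i],
                              df$high[i])))
}

#' Write / read a scenario specification as tidy CSV
#'
#' Columns `scenario_id`, `source`, `year`, `factor`.
#'
#' @param spec A [scenario_spec()].
#' @param path File path.
#' @return `write_scenario_csv()` returns `path` invisibly;
#'   `read_scenario_csv()` returns a [scenario_spec()].
#' @export
write_scenario_csv <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  rows <- lapply(names(spec$factors), function(src) {
    f <- spec$factors[[src]]
    data.frame(scenario_id = spec$scenario_id, source = src,
               year = series_years(f), factor = f$values,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenario_csv
#' @export
read_scenario_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("scenario_id", "source", "year", "factor"), path)
  sid <- unique(df$scenario_id)
  if (length(sid) != 1L)
    stop(sprintf("'%s' must hold exactly one scenario", path), call. = FALSE)
  factors <- lapply(split(df, df$source), function(sub) {
    sub <- sub[order(sub$year), ]
    check_contiguous(sub$year, sprintf("%s (source %s)", path,
                                       sub$source[1L]))
    annual_series(sub$year[1L], sub$factor, "1")
  })
  scenario_spec(sid, factors)
}

#' Write a pipeline report as JSON
#'
#' @param report A report list from [run_pipeline()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  plain <- unclass(report)
  attributes(plain) <- list(names = names(plain))
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
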