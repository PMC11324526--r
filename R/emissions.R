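# Assembly of anthropogenic Nr emission and flux series: factorial
# attribution of the terrestrial ensemble, the soil/livestock NH3 rescaling,
# and the inventory + soil-flux totals.

NR_SPECIES <- c("NOx-N", "NH3-N", "N2O-N", "CH4", "CO", "VOC")
INVENTORY_SECTORS <- c("agriculture", "energy", "industry", "residential",
                       "shipping", "solvents", "transportation", "waste")
FLUX_KINDS <- c("NBP", "soilN2O", "soilNOx", "soilNH3")
NR_DRIVERS <- c("fertilizer", "manure", "Ndep", "irrigation", "LUC", "CO2",
                "climate")

#' One factorial terrestrial-model run
#'
#' A single (model, experiment, flux kind) output series from a factorial
#' terrestrial-ensemble design.  Net biome productivity (NBP) may be signed;
#' soil emission fluxes are non-negative.
#'
#' @param model_id Model label, e.g. `"M1"`.
#' @param experiment_id Experiment label from the declared design, e.g.
#'   `"SH1"` or `"SH12"`.
#' @param flux_kind One of `"NBP"`, `"soilN2O"`, `"soilNOx"`, `"soilNH3"`.
#' @param series An [annual_series()] (PgC yr-1 for NBP, TgN yr-1 otherwise).
#' @return A list of class `factorial_run`.
#' @export
factorial_run <- function(model_id, experiment_id, flux_kind, series) {
  flux_kind <- match.arg(flux_kind, FLUX_KINDS)
  stopifnot(is_annual_series(series), nzchar(model_id), nzchar(experiment_id))
  structure(list(model_id = model_id, experiment_id = experiment_id,
                 flux_kind = flux_kind, series = series),
            class = "factorial_run")
}

#' Factorial experiment design
#'
#' Declares, per driver, the ordered pair of experiments whose difference
#' isolates that driver (first minus second), and optionally the experiment
#' representing the natural (all-anthropogenic-drivers-off) baseline.
#'
#' @param driver_rules Named list mapping each driver to a length-2 character
#'   vector `c(experiment_on, experiment_off)`.
#' @param natural_experiment Optional experiment id whose ensemble mean is
#'   reported as the `"natural"` baseline flux.
#' @return A list of class `experiment_design`.
#' @seealso [default_experiment_design()]
#' @export
experiment_design <- function(driver_rules, natural_experiment = NULL) {
  stopifnot(is.list(driver_rules), length(driver_rules) >= 1L)
  bad <- setdiff(names(driver_rules), NR_DRIVERS)
  if (length(bad))
    stop("unknown drivers in design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (d in names(driver_rules)) {
    pair <- driver_rules[[d]]
    if (!is.character(pair) || length(pair) != 2L)
      stop(sprintf("driver '%s' needs an ordered pair of experiment ids", d),
           call. = FALSE)
  }
  if ("LUC" %in% names(driver_rules) &&
      !identical(driver_rules[["LUC"]], c("SH12", "SH11")))
    stop("the LUC rule must be the (SH12, SH11) pair", call. = FALSE)
  structure(list(driver_rules = driver_rules,
                 natural_experiment = natural_experiment),
            class = "experiment_design")
}

#' Default factorial design
#'
#' Single-factor-off differencing against the all-drivers-on run `SH1` for
#' fertilizer, manure, N deposition, irrigation, CO2 and climate; land-use
#' change as `SH12 - SH11` (which avoids confounding with fertilizer and
#' manure changes); natural baseline from the all-off run `SH9`.  The full
#' experiment table of the source ensemble is not fixed here, so the design
#' is user-overridable via [experiment_design()].
#'
#' @return An `experiment_design`.
#' @export
default_experiment_design <- function() {
  experiment_design(
    driver_rules = list(
      fertilizer = c("SH1", "SH2"),
      manure     = c("SH1", "SH3"),
      Ndep       = c("SH1", "SH4"),
      irrigation = c("SH1", "SH5"),
      CO2        = c("SH1", "SH7"),
      climate    = c("SH1", "SH8"),
      LUC        = c("SH12", "SH11")
    ),
    natural_experiment = "SH9"
  )
}

new_driver_attribution <- function(driver, flux_kind, mean, sd, n_models,
                                   models) {
  check_same_axis(mean, sd, "attribution mean/sd")
  if (any(sd$values < 0)) stop("attribution sd must be non-negative",
                               call. = FALSE)
  structure(list(driver = driver, flux_kind = flux_kind, mean = mean,
                 sd = sd, n_models = n_models, models = models),
            class = "driver_attribution")
}

ensemble_stats <- function(contribs, driver, flux_kind) {
  mat <- do.call(rbind, lapply(contribs, function(s) s$values))
  first <- contribs[[1L]]
  mu <- colMeans(mat)
  sdv <- if (nrow(mat) >= 2L) apply(mat, 2L, stats::sd) else rep(0, ncol(mat))
  new_driver_attribution(
    driver, flux_kind,
    mean = annual_series(first$start_year, mu, first$units),
    sd = annual_series(first$start_year, sdv, first$units),
    n_models = nrow(mat), models = names(contribs)
  )
}

#' Attribute driver contributions from a factorial ensemble
#'
#' For every flux kind present in `runs` and every driver in the design,
#' computes the per-model contribution as the difference of the driver's
#' experiment pair (first minus second), then the ensemble mean and 1 sample
#' standard deviation (n-1 denominator) across the models that provide both
#' experiments.  Flux-kind availability may differ by model; a model missing
#' an experiment is excluded from that driver with a warning, and an empty
#' ensemble is an error.  When the design declares a natural baseline
#' experiment its ensemble mean is returned as driver `"natural"`.
#'
#' @param runs List of [factorial_run()] objects.
#' @param design An [experiment_design()].
#' @return A named list of class `attribution_set`; elements are
#'   `driver_attribution` objects keyed `"<flux_kind>.<driver>"`.
#' @seealso [get_attribution()], [anthropogenic_nr_soil_flux()]
#' @export
attribute_drivers <- function(runs, design = default_experiment_design()) {
  stopifnot(inherits(design, "experiment_design"), length(runs) >= 1L)
  for (r in runs) stopifnot(inherits(r, "factorial_run"))
  out <- list()
  flux_kinds <- unique(vapply(runs, function(r) r$flux_kind, ""))
  for (fk in flux_kinds) {
    rk <- Filter(function(r) r$flux_kind == fk, runs)
    models <- unique(vapply(rk, function(r) r$model_id, ""))
    lookup <- stats::setNames(
      rk, vapply(rk, function(r) paste(r$model_id, r$experiment_id,
                                       sep = "\r"), ""))
    targets <- design$driver_rules
    if (!is.null(design$natural_experiment))
      targets <- c(targets,
                   list(natural = rep(design$natural_experiment, 2L)))
    for (d in names(targets)) {
      pair <- targets[[d]]
      contribs <- list()
      for (m in models) {
        a <- lookup[[paste(m, pair[1L], sep = "\r")]]
        b <- lookup[[paste(m, pair[2L], sep = "\r")]]
        if (is.null(a) || is.null(b)) {
          warning(sprintf(
            "model '%s' lacks experiment pair (%s, %s) for %s/%s; excluded",
            m, pair[1L], pair[2L], fk, d), call. = FALSE)
          next
        }
        contribs[[m]] <- if (d == "natural") a$series else a$series - b$series
      }
      if (!length(contribs))
        stop(sprintf("empty ensemble for %s/%s: no model has both %s and %s",
                     fk, d, pair[1L], pair[2L]), call. = FALSE)
      out[[paste(fk, d, sep = ".")]] <- ensemble_stats(contribs, d, fk)
    }
  }
  structure(out, class = "attribution_set")
}

#' Retrieve one driver attribution from an attribution set
#'
#' @param attribs An `attribution_set` from [attribute_drivers()].
#' @param flux_kind Flux kind label.
#' @param driver Driver label (a design driver, `"natural"`, or the
#'   composite `"anthropogenic_Nr"` once computed).
#' @return A `driver_attribution`.
#' @export
get_attribution <- function(attribs, flux_kind, driver) {
  key <- paste(flux_kind, driver, sep = ".")
  a <- attribs[[key]]
  if (is.null(a))
    stop(sprintf("no attribution for %s/%s", flux_kind, driver),
         call. = FALSE)
  a
}

#' Direct anthropogenic Nr contribution to a soil flux
#'
#' Sums the fertilizer, manure and N-deposition attribution means for one
#' flux kind -- the drivers that directly add reactive nitrogen to
#' ecosystems -- and combines their ensemble spreads in quadrature.
#'
#' @inheritParams get_attribution
#' @return A `driver_attribution` with driver `"anthropogenic_Nr"`.
#' @export
anthropogenic_nr_soil_flux <- function(attribs, flux_kind) {
  parts <- lapply(c("fertilizer", "manure", "Ndep"),
                  function(d) get_attribution(attribs, flux_kind, d))
  m <- series_sum(lapply(parts, function(p) p$mean))
  var_sum <- Reduce(`+`, lapply(parts, function(p) p$sd$values^2))
  s <- annual_series(m$start_year, sqrt(var_sum), m$units)
  new_driver_attribution("anthropogenic_Nr", flux_kind, m, s,
                         n_models = min(vapply(parts, function(p)
                           p$n_models, 0L)),
                         models = parts[[1L]]$models)
}

#' Rescale soil and livestock NH3 emissions to an agricultural anchor
#'
#' The agricultural NH3 total in 2019 is split into a soil component (fixed
#' fraction, default 48%) and a livestock component (the remainder, 52%).
#' The soil component follows the temporal shape of the ensemble soil-NH3
#' series normalized to its 2019 value; the livestock component follows a
#' configurable trajectory shape (default: the same soil shape, since the
#' livestock time evolution is not independently constrained).
#'
#' @param agri_total_2019 Total agricultural NH3 emission in 2019, TgN yr-1.
#' @param ensemble_soil_nh3 Ensemble anthropogenic soil-NH3 series
#'   ([annual_series()], TgN yr-1) covering 2019 with a nonzero 2019 value.
#' @param soil_fraction Soil share of the 2019 agricultural total (0.48).
#' @param livestock_shape Optional dimensionless [annual_series()] giving the
#'   livestock trajectory relative to 2019; default reuses the soil shape.
#' @return A list with [annual_series()] elements `soil`, `livestock` and
#'   `total` (their sum).
#' @examples
#' shp <- annual_series(2017, c(30, 35, 39), "TgN yr-1")
#' scale_soil_nh3(38.2, shp)$soil$values[3]  # 0.48 * 38.2 = 18.336
#' @export
scale_soil_nh3 <- function(agri_total_2019, ensemble_soil_nh3,
                           soil_fraction = 0.48, livestock_shape = NULL) {
  stopifnot(is_annual_series(ensemble_soil_nh3),
            soil_fraction > 0, soil_fraction < 1)
  if (!is.finite(agri_total_2019) || agri_total_2019 <= 0)
    stop("agri_total_2019 must be a positive emission total", call. = FALSE)
  anchor <- series_value(ensemble_soil_nh3, 2019L)
  if (anchor == 0)
    stop("soil NH3 series has a zero 2019 value; cannot anchor the rescaling",
         call. = FALSE)
  shape <- ensemble_soil_nh3$values / anchor
  soil <- annual_series(ensemble_soil_nh3$start_year,
                        soil_fraction * agri_total_2019 * shape, "TgN yr-1")
  lshape <- if (is.null(livestock_shape)) shape else {
    stopifnot(is_annual_series(livestock_shape))
    check_same_axis(ensemble_soil_nh3, livestock_shape, "NH3 shapes")
    if (series_value(livestock_shape, 2019L) != 1)
      stop("livestock_shape must equal 1 in 2019", call. = FALSE)
    livestock_shape$values
  }
  livestock <- annual_series(ensemble_soil_nh3$start_year,
                             (1 - soil_fraction) * agri_total_2019 * lshape,
                             "TgN yr-1")
  list(soil = soil, livestock = livestock, total = soil + livestock)
}

#' Sum an inventory species across sectors
#'
#' @param inventory Long-format inventory data frame with columns `year`,
#'   `species`, `sector`, `value`, `units`.
#' @param species Species label, e.g. `"NOx-N"`.
#' @param sectors Sectors to include; default all present.
#' @return An [annual_series()].
#' @export
inventory_series <- function(inventory, species, sectors = NULL) {
  stopifnot(is.data.frame(inventory),
            all(c("year", "species", "sector", "value", "units") %in%
                  names(inventory)))
  sub <- inventory[inventory$species == species, , drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("species '%s' absent from the inventory", species),
         call. = FALSE)
  if (!is.null(sectors)) {
    sub <- sub[sub$sector %in% sectors, , drop = FALSE]
    if (!nrow(sub))
      stop(sprintf("no sectors %s for species '%s'",
                   paste(sectors, collapse = "/"), species), call. = FALSE)
  }
  units <- unique(sub$units)
  if (length(units) != 1L)
    stop(sprintf("inconsistent units for species '%s'", species),
         call. = FALSE)
  agg <- stats::aggregate(value ~ year, data = sub, FUN = sum)
  agg <- agg[order(agg$year), ]
  yrs <- agg$year
  if (!identical(as.integer(yrs), seq(yrs[1L], yrs[length(yrs)]))) {
    missing <- setdiff(seq(yrs[1L], yrs[length(yrs)]), yrs)
    stop(sprintf("non-contiguous years for species '%s'; missing: %s",
                 species, paste(missing, collapse = ", ")), call. = FALSE)
  }
  annual_series(yrs[1L], agg$value, units)
}

#' Total anthropogenic emissions of one species
#'
#' Fossil-fuel aggregate (sum of all inventory sectors except agriculture)
#' plus any attributed anthropogenic soil components.  The agriculture
#' sector is handled only through the soil/livestock pathways so that
#' agricultural emissions are never double counted.
#'
#' @inheritParams inventory_series
#' @param soil Optional list of [annual_series()] soil (or livestock)
#'   components to add, on the same year axis as the inventory.
#' @return An [annual_series()].
#' @export
total_anthropogenic_emissions <- function(inventory, species, soil = NULL) {
  fossil <- inventory_series(inventory, species,
                             sectors = setdiff(INVENTORY_SECTORS,
                                               "agriculture"))
  if (is.null(soil) || !length(soil)) return(fossil)
  if (is_annual_series(soil)) soil <- list(soil)
  for (s in soil) check_same_axis(fossil, s, sprintf("%s totals", species))
  fossil + series_sum(soil)
}
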