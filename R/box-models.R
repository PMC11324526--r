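# One-box atmospheric models: cumulative CO2 perturbation, N2O mass balance
# with a fixed perturbation lifetime, and the CH4 box with an OH-lifetime
# that responds to CH4 self-feedback, NOx/CO/VOC emission changes and
# temperature.

N2O_CATEGORIES <- c("FF", "soil", "BB", "AREC", "chem", "NREC", "ocean")

#' Gas concentration trajectory
#'
#' @param species `"CO2"`, `"N2O"` or `"CH4"`.
#' @param concentration An [annual_series()]; ppmv for the CO2 perturbation,
#'   ppbv for N2O, ppb for CH4.
#' @return A list of class `gas_trajectory`.
#' @export
gas_trajectory <- function(species, concentration) {
  species <- match.arg(species, c("CO2", "N2O", "CH4"))
  stopifnot(is_annual_series(concentration))
  if (species != "CO2" && any(concentration$values <= 0))
    stop(sprintf("%s concentrations must be positive", species),
         call. = FALSE)
  structure(list(species = species, concentration = concentration),
            class = "gas_trajectory")
}

#' N2O source set by category
#'
#' The seven emission categories of the N2O mass balance: fossil fuel (FF),
#' soil, biomass burning (BB), anthropogenic river/estuary/coastal (AREC),
#' atmospheric chemistry, natural river/estuary/coastal (NREC) and open
#' ocean.  All categories must be present (zeros allowed) on one shared
#' year axis, in TgN yr-1.
#'
#' @param FF,soil,BB,AREC,chem,NREC,ocean [annual_series()] per category.
#' @return A named list of class `n2o_sources`.
#' @export
n2o_sources <- function(FF, soil, BB, AREC, chem, NREC, ocean) {
  src <- list(FF = FF, soil = soil, BB = BB, AREC = AREC, chem = chem,
              NREC = NREC, ocean = ocean)
  for (nm in names(src)) {
    stopifnot(is_annual_series(src[[nm]]))
    check_units(src[[nm]], "TgN yr-1", sprintf("N2O source '%s'", nm))
    check_same_axis(src[[1L]], src[[nm]], "N2O sources")
  }
  structure(src, class = "n2o_sources")
}

#' Constant-in-time N2O source set
#'
#' Convenience builder: one constant value per category over a year range.
#'
#' @param values Named numeric vector over the seven categories, TgN yr-1.
#' @param start_year,end_year Inclusive year range.
#' @return An [n2o_sources()] set.
#' @export
constant_n2o_sources <- function(values, start_year, end_year) {
  stopifnot(all(N2O_CATEGORIES %in% names(values)))
  n <- end_year - start_year + 1L
  do.call(n2o_sources, lapply(as.list(values[N2O_CATEGORIES]), function(v)
    annual_series(start_year, rep(v, n), "TgN yr-1")))
}

#' Atmospheric CO2 perturbation from nitrogen-driven carbon uptake
#'
#' The change in atmospheric CO2 (ppmv) attributable to anthropogenic Nr is
#' the running cumulative sum of the NBP contributions of fertilizer, manure
#' and N deposition, multiplied by `-alpha / delta_co2`: land carbon uptake
#' (positive NBP) draws CO2 down, and only the airborne fraction `alpha` of
#' the perturbation remains in the atmosphere after ocean exchange.
#'
#' @param nbp_fertilizer,nbp_manure,nbp_ndep [annual_series()] NBP
#'   contributions, PgC yr-1, on one shared axis.
#' @param p A [gas_box_params()] set.
#' @return A [gas_trajectory()] (species `"CO2"`, ppmv) whose value in year
#'   y is the 1850-to-y concentration change.
#' @export
co2_perturbation <- function(nbp_fertilizer, nbp_manure, nbp_ndep,
                             p = gas_box_params()) {
  for (s in list(nbp_fertilizer, nbp_manure, nbp_ndep)) {
    stopifnot(is_annual_series(s))
    check_units(s, "PgC yr-1", "NBP contribution")
    check_same_axis(nbp_fertilizer, s, "NBP contributions")
  }
  total <- nbp_fertilizer + nbp_manure + nbp_ndep
  dco2 <- annual_series(total$start_year,
                        -cumsum(total$values) * p$alpha / p$delta_co2,
                        "ppmv")
  structure(list(species = "CO2", concentration = dco2),
            class = "gas_trajectory")
}

# Shared Euler driver: step conc with dC/dt = E/delta - C/tau, where tau may
# be state-dependent (CH4).  `substeps` refines the annual step; 1 is the
# package default, 12 serves as the cross-check oracle in tests.
euler_box <- function(emissions, delta, tau_fun, init, substeps) {
  n <- length(emissions)
  conc <- numeric(n)
  conc[1L] <- init
  dt <- 1 / substeps
  for (t in seq_len(n - 1L)) {
    c_now <- conc[t]
    for (k in seq_len(substeps)) {
      tau <- tau_fun(c_now, t)
      c_now <- c_now + dt * (emissions[t] / delta - c_now / tau)
    }
    conc[t + 1L] <- c_now
  }
  if (any(!is.finite(conc)))
    stop("box-model integration produced non-finite concentrations",
         call. = FALSE)
  conc
}

#' Integrate the one-box N2O mass balance
#'
#' Annual explicit-Euler integration of
#' `d[N2O]/dt = sum(E) / delta_n2o - [N2O] / tau_n2o`.  Under constant
#' sources the trajectory approaches the steady state
#' `tau_n2o * sum(E) / delta_n2o`.
#'
#' @param sources An [n2o_sources()] set.
#' @param p A [gas_box_params()] set.
#' @param init_ppbv Initial concentration (ppbv, positive).  Default: the
#'   steady state implied by the first-year sources.
#' @param substeps Euler substeps per year (default 1, the package's
#'   integration convention; larger values refine the step for
#'   cross-checking).
#' @return A [gas_trajectory()] (species `"N2O"`, ppbv), on the source axis;
#'   the value at year y is the concentration at the start of year y.
#' @export
n2o_integrate <- function(sources, p = gas_box_params(), init_ppbv = NULL,
                          substeps = 1L) {
  stopifnot(inherits(sources, "n2o_sources"), substeps >= 1L)
  total <- series_sum(unclass(sources))
  if (any(total$values < 0))
    warning("negative total N2O source in some years (perturbation run?)",
            call. = FALSE)
  if (is.null(init_ppbv))
    init_ppbv <- p$tau_n2o * total$values[1L] / p$delta_n2o
  if (!is.finite(init_ppbv) || init_ppbv <= 0)
    stop("init_ppbv must be positive", call. = FALSE)
  conc <- euler_box(total$values, p$delta_n2o,
                    function(c_now, t) p$tau_n2o, init_ppbv, substeps)
  gas_trajectory("N2O", annual_series(total$start_year, conc, "ppbv"))
}

#' Reconstruct total N2O sources from a concentration trajectory
#'
#' Inverts the annual Euler step of the N2O box:
#' `E[t] = delta_n2o * (C[t+1] - C[t] + C[t] / tau_n2o)`.  Given a
#' trajectory generated by [n2o_integrate()] with `substeps = 1`, this
#' recovers the total source series (its last year is unconstrained).
#'
#' @param trajectory A [gas_trajectory()] for N2O.
#' @param p A [gas_box_params()] set.
#' @return An [annual_series()] of implied total sources (TgN yr-1), one
#'   year shorter than the trajectory.
#' @export
n2o_implied_sources <- function(trajectory, p = gas_box_params()) {
  stopifnot(inherits(trajectory, "gas_trajectory"),
            trajectory$species == "N2O")
  cc <- trajectory$concentration$values
  if (length(cc) < 2L) stop("trajectory too short to invert", call. = FALSE)
  e <- p$delta_n2o * (diff(cc) + cc[-length(cc)] / p$tau_n2o)
  annual_series(trajectory$concentration$start_year, e, "TgN yr-1")
}

#' CH4 lifetime with the OH feedback
#'
#' The OH loss frequency is the reference frequency `1/tau_oh0` modulated by
#' a power-law CH4 self-feedback, an exponential response to NOx/CO/VOC
#' emission departures from the 2005 reference, and an additive temperature
#' term inside the bracket:
#' `1/tau_oh = (1/tau_oh0) * ((CH4/CH4_ref)^s_oh *
#'   exp(s_nox*dE_nox + s_co*dE_co + s_voc*dE_voc) + s_t*dT)`.
#' The composite lifetime combines the OH branch harmonically with the
#' stratospheric, soil-uptake and tropospheric-chlorine losses.
#'
#' @param ch4_ppb Current CH4 concentration, ppb (positive).
#' @param dE_nox,dE_co,dE_voc Emission departures from the 2005 reference
#'   (anthropogenic + biomass burning), Tg N / Tg CO / Tg VOC per year.
#' @param dT Global-mean surface temperature departure from 2005, K.
#' @param p A [gas_box_params()] set.
#' @return A list with elements `tau_oh` and `tau_ch4` (years).
#' @examples
#' ch4_lifetime(1783.36)$tau_oh   # 11.17 at the reference state
#' ch4_lifetime(1783.36)$tau_ch4  # ~9.13 (harmonic sum with 120/150/200)
#' @export
ch4_lifetime <- function(ch4_ppb, dE_nox = 0, dE_co = 0, dE_voc = 0, dT = 0,
                         p = gas_box_params()) {
  if (!is.finite(ch4_ppb) || ch4_ppb <= 0)
    stop("ch4_ppb must be positive", call. = FALSE)
  bracket <- (ch4_ppb / p$ch4_ref)^p$s_oh *
    exp(p$s_nox * dE_nox + p$s_co * dE_co + p$s_voc * dE_voc) +
    p$s_t * dT
  inv_oh <- bracket / p$tau_oh0
  inv_total <- inv_oh + 1 / p$tau_strat + 1 / p$tau_soil + 1 / p$tau_tropcl
  list(tau_oh = 1 / inv_oh, tau_ch4 = 1 / inv_total)
}

#' Integrate the one-box CH4 mass balance with the OH-lifetime feedback
#'
#' Annual explicit-Euler stepping of
#' `d[CH4]/dt = -[CH4]/tau_ch4 + E/delta_ch4` with the composite lifetime
#' re-evaluated at every step from the current concentration and that
#' year's emission/temperature departures (see [ch4_lifetime()]).
#'
#' @param emissions_total Total CH4 emissions (anthropogenic + biomass
#'   burning + natural), [annual_series()], Tg yr-1.
#' @param dE_nox,dE_co,dE_voc [annual_series()] emission departures from the
#'   2005 reference, on the same axis as `emissions_total`.
#' @param dT [annual_series()] temperature departure from 2005, K.
#' @param p A [gas_box_params()] set.
#' @param init_ppb Initial CH4 concentration (ppb).  Default: steady state
#'   implied by the first-year emissions and lifetime at the reference
#'   concentration.
#' @param substeps Euler substeps per year (default 1; see
#'   [n2o_integrate()]).
#' @param fixed_lifetime Optional lifetime in years; when given, the
#'   feedback is disabled and this lifetime is used throughout (a testing
#'   hook for the closed-form steady state).
#' @return A [gas_trajectory()] (species `"CH4"`, ppb).
#' @export
ch4_integrate <- function(emissions_total, dE_nox, dE_co, dE_voc, dT,
                          p = gas_box_params(), init_ppb = NULL,
                          substeps = 1L, fixed_lifetime = NULL) {
  stopifnot(is_annual_series(emissions_total), substeps >= 1L)
  check_units(emissions_total, "Tg yr-1", "CH4 emissions")
  for (s in list(dE_nox, dE_co, dE_voc, dT)) {
    stopifnot(is_annual_series(s))
    check_same_axis(emissions_total, s, "CH4 box inputs")
  }
  tau_fun <- if (!is.null(fixed_lifetime)) {
    stopifnot(fixed_lifetime > 0)
    function(c_now, t) fixed_lifetime
  } else {
    function(c_now, t)
      ch4_lifetime(c_now, dE_nox$values[t], dE_co$values[t],
                   dE_voc$values[t], dT$values[t], p)$tau_ch4
  }
  if (is.null(init_ppb)) {
    tau0 <- if (!is.null(fixed_lifetime)) fixed_lifetime else
      ch4_lifetime(p$ch4_ref, dE_nox$values[1L], dE_co$values[1L],
                   dE_voc$values[1L], dT$values[1L], p)$tau_ch4
    init_ppb <- tau0 * emissions_total$values[1L] / p$delta_ch4
  }
  if (!is.finite(init_ppb) || init_ppb <= 0)
    stop("init_ppb must be positive", call. = FALSE)
  conc <- euler_box(emissions_total$values, p$delta_ch4, tau_fun, init_ppb,
                    substeps)
  gas_trajectory("CH4", annual_series(emissions_total$start_year, conc,
                                      "ppb"))
}

#' Concentration effect of anthropogenic Nr from a paired run
#'
#' The per-year difference between a trajectory computed with anthropogenic
#' Nr sources and one computed without them.
#'
#' @param run_with,run_without [gas_trajectory()] objects of the same
#'   species on identical year axes.
#' @return An [annual_series()] of concentration differences (with minus
#'   without).
#' @export
nr_concentration_effect <- function(run_with, run_without) {
  stopifnot(inherits(run_with, "gas_trajectory"),
            inherits(run_without, "gas_trajectory"))
  if (!identical(run_with$species, run_without$species))
    stop(sprintf("species mismatch: '%s' vs '%s'", run_with$species,
                 run_without$species), call. = FALSE)
  run_with$concentration - run_without$concentration
}
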