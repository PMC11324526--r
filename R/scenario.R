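# Linear forward projection of per-agent and net direct radiative forcing
# under per-source scaling-factor scenarios anchored at 2019.

SCENARIO_SOURCES <- c("fertilizer", "manure", "Ndep", "FF_NOx", "FF_N2O",
                      "FF_NH3", "soil_NOx", "soil_NH3", "soil_N2O")

#' Scenario specification
#'
#' Per-source dimensionless scaling-factor trajectories relative to 2019.
#' Every factor series must include 2019 with the value 1 and be
#' non-negative throughout.
#'
#' @param scenario_id Label, e.g. `"cleaner"`.
#' @param factors Named list over all nine sources: fertilizer, manure,
#'   Ndep, FF_NOx, FF_N2O, FF_NH3, soil_NOx, soil_NH3, soil_N2O; each a
#'   dimensionless [annual_series()].
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id, factors) {
  missing <- setdiff(SCENARIO_SOURCES, names(factors))
  if (length(missing))
    stop("missing scenario sources: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in SCENARIO_SOURCES) {
    f <- factors[[nm]]
    stopifnot(is_annual_series(f))
    if (any(f$values < 0))
      stop(sprintf("factor '%s' has negative values", nm), call. = FALSE)
    anchor <- series_value(f, 2019L)
    if (abs(anchor - 1) > 1e-9)
      stop(sprintf("factor '%s' must equal 1.0 in 2019 (got %g)", nm,
                   anchor), call. = FALSE)
  }
  structure(list(scenario_id = scenario_id,
                 factors = factors[SCENARIO_SOURCES]),
            class = "scenario_spec")
}

#' 2019 baseline state for scenario projection
#'
#' The 2019 anchor of the projector: per-agent 2019 forcings (relative to
#' 1850) with their bounds, 2019 greenhouse-gas concentrations, 2019
#' emission totals split into fossil/soil (and livestock for NH3)
#' components, the present-day (2015-2019 mean) NBP contribution per Nr
#' driver, the 2019 N2O source magnitudes by category with the soil
#' anthropogenic part split by driver, the 2019 total CH4 emission, and the
#' 2019 departures of NOx/CO/VOC emissions and temperature from the 2005
#' CH4-lifetime reference.
#'
#' The forcing defaults are the study's diagnosed values
#' ([historical_forcing_2019()]); the remaining defaults are consistent
#' with the package's calibrated synthetic fixture.
#'
#' @param rf A five-agent `forcing_components` data frame of 2019 forcings.
#' @param n2o_ppbv,ch4_ppb 2019 concentrations.
#' @param nox_ff,nox_soil 2019 NOx emissions, fossil and anthropogenic
#'   soil, TgN yr-1.
#' @param nh3_ff,nh3_soil,nh3_livestock 2019 NH3 emissions, TgN yr-1.
#' @param nbp_drivers Named numeric: present-day NBP contribution of
#'   `fertilizer`, `manure`, `Ndep`, PgC yr-1.
#' @param n2o_ff 2019 fossil-fuel N2O source, TgN yr-1.
#' @param n2o_soil_drivers Named numeric: 2019 anthropogenic soil N2O by
#'   driver (`fertilizer`, `manure`, `Ndep`), TgN yr-1.
#' @param n2o_other Named numeric over the non-scaled categories
#'   (`soil_natural`, `BB`, `AREC`, `chem`, `NREC`, `ocean`), TgN yr-1.
#' @param ch4_emissions_total 2019 total CH4 emission (anthropogenic +
#'   biomass burning + natural), Tg yr-1.
#' @param de_nox,de_co,de_voc 2019 emission departures from 2005, Tg yr-1.
#' @param dt_2019 2019 temperature departure from 2005, K.
#' @return A list of class `baseline_2019`.
#' @export
baseline_2019 <- function(rf = historical_forcing_2019(),
                          n2o_ppbv = 332, ch4_ppb = 1866,
                          nox_ff = 43.4, nox_soil = 3.1,
                          nh3_ff = 12.3, nh3_soil = 18.336,
                          nh3_livestock = 19.864,
                          nbp_drivers = c(fertilizer = 0.30, manure = 0.15,
                                          Ndep = 0.10),
                          n2o_ff = 2.0,
                          n2o_soil_drivers = c(fertilizer = 1.85,
                                               manure = 0.85, Ndep = 0.80),
                          n2o_other = c(soil_natural = 6.2, BB = 0.7,
                                        AREC = 0.4, chem = 0.4, NREC = 0.3,
                                        ocean = 3.4),
                          ch4_emissions_total = 620,
                          de_nox = -1.5, de_co = -80, de_voc = 10,
                          dt_2019 = 0.45) {
  stopifnot(is.data.frame(rf), setequal(rf$agent, FORCING_AGENTS),
            n2o_ppbv > 0, ch4_ppb > 0,
            all(c("fertilizer", "manure", "Ndep") %in% names(nbp_drivers)),
            all(c("fertilizer", "manure", "Ndep") %in%
                  names(n2o_soil_drivers)),
            all(c("soil_natural", "BB", "AREC", "chem", "NREC", "ocean") %in%
                  names(n2o_other)),
            ch4_emissions_total > 0)
  vals <- c(n2o_ppbv, ch4_ppb, nox_ff, nox_soil, nh3_ff, nh3_soil,
            nh3_livestock, nbp_drivers, n2o_ff, n2o_soil_drivers, n2o_other,
            ch4_emissions_total, de_nox, de_co, de_voc, dt_2019,
            rf$central, rf$low, rf$high)
  if (!all(is.finite(vals)))
    stop("all baseline fields must be finite", call. = FALSE)
  structure(list(rf = rf, n2o_ppbv = n2o_ppbv, ch4_ppb = ch4_ppb,
                 nox_ff = nox_ff, nox_soil = nox_soil, nh3_ff = nh3_ff,
                 nh3_soil = nh3_soil, nh3_livestock = nh3_livestock,
                 nbp_drivers = nbp_drivers, n2o_ff = n2o_ff,
                 n2o_soil_drivers = n2o_soil_drivers, n2o_other = n2o_other,
                 ch4_emissions_total = ch4_emissions_total,
                 de_nox = de_nox, de_co = de_co, de_voc = de_voc,
                 dt_2019 = dt_2019),
            class = "baseline_2019")
}

rf_of <- function(rf, agent, col = "central") rf[[col]][rf$agent == agent]

factor_values <- function(spec, source, years) {
  f <- spec$factors[[source]]
  vapply(years, function(y) series_value(f, y), 0)
}

#' Project per-agent and net forcing under a scenario
#'
#' Projects the direct radiative forcing of anthropogenic Nr (relative to
#' 1850) from the 2019 baseline to `horizon_year` under per-source scaling
#' factors:
#' * CO2: the 2019 forcing accumulates annual increments
#'   `-(NBP_fert*f_fert + NBP_manure*f_manure + NBP_Ndep*f_Ndep) *
#'   alpha/delta_co2 * s_co2`, i.e. scaled present-day NBP contributions
#'   drawn forward year by year (land uptake cools).
#' * N2O and CH4: the box models continue from the 2019 concentrations with
#'   scaled sources (fossil N2O follows its own factor, soil anthropogenic
#'   N2O scales per driver; the CH4 lifetime responds to the scaled NOx
#'   total), and the concentration changes map to forcing through the
#'   radiative sensitivities.
#' * Aerosols: the 2019 forcing scaled by the (NOx + NH3) emission ratio to
#'   2019; O3: scaled by the NOx ratio.  Both are exactly homogeneous of
#'   degree 1 in their emission totals.
#' * Net: the per-year sum of the five agents.
#'
#' Projection bounds inherit the historical percentage ranges: each agent's
#' low/high track its central value multiplied by the 2019 low/central and
#' high/central ratios.
#'
#' @param spec A [scenario_spec()] covering 2019..`horizon_year`.
#' @param base A [baseline_2019()].
#' @param p A [gas_box_params()] set.
#' @param s A [sensitivity_constants()] set.
#' @param horizon_year Last projected year (default 2060).
#' @param uncertainty Attach multiplicative bounds (default `TRUE`).
#' @param nbp_saturation Optional dimensionless ceiling on the effective
#'   N-input scaling of the NBP response: emulates nitrogen saturation of
#'   the land carbon sink by capping each driver factor inside the CO2
#'   term (the other pathways are unaffected).  Default `NULL`, i.e. the
#'   fully linear response.
#' @return A data frame of class `nr_projection` with columns `year`,
#'   `agent` (five agents plus `"net"`), `central`, `low`, `high` (W m-2),
#'   and attributes `scenario_id` and `trajectories` (the projected N2O and
#'   CH4 [gas_trajectory()] objects).
#' @export
project_forcing <- function(spec, base = baseline_2019(),
                            p = gas_box_params(),
                            s = sensitivity_constants(),
                            horizon_year = 2060, uncertainty = TRUE,
                            nbp_saturation = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(base, "baseline_2019"),
            horizon_year > 2019)
  years <- 2019:horizon_year
  n <- length(years)
  f <- lapply(stats::setNames(SCENARIO_SOURCES, SCENARIO_SOURCES),
              function(src) factor_values(spec, src, years))

  # CO2 (cumulative scaled land uptake; optional saturation ceiling)
  sat <- function(x) if (is.null(nbp_saturation)) x
                     else pmin(x, nbp_saturation)
  nbp_scaled <- base$nbp_drivers[["fertilizer"]] * sat(f$fertilizer) +
    base$nbp_drivers[["manure"]] * sat(f$manure) +
    base$nbp_drivers[["Ndep"]] * sat(f$Ndep)
  inc <- -nbp_scaled * p$alpha / p$delta_co2 * s$s_co2
  inc[1L] <- 0  # 2019 is the anchor; accumulation starts in 2020
  rf_co2 <- rf_of(base$rf, "CO2") + cumsum(inc)

  # N2O box continued from 2019
  soil_anthro <- (base$n2o_soil_drivers[["fertilizer"]] * f$fertilizer +
                  base$n2o_soil_drivers[["manure"]] * f$manure +
                  base$n2o_soil_drivers[["Ndep"]] * f$Ndep) * f$soil_N2O
  mk <- function(v) annual_series(2019L, v, "TgN yr-1")
  const <- function(x) rep(x, n)
  n2o_src <- n2o_sources(
    FF = mk(base$n2o_ff * f$FF_N2O),
    soil = mk(base$n2o_other[["soil_natural"]] + soil_anthro),
    BB = mk(const(base$n2o_other[["BB"]])),
    AREC = mk(const(base$n2o_other[["AREC"]])),
    chem = mk(const(base$n2o_other[["chem"]])),
    NREC = mk(const(base$n2o_other[["NREC"]])),
    ocean = mk(const(base$n2o_other[["ocean"]]))
  )
  n2o_traj <- n2o_integrate(n2o_src, p, init_ppbv = base$n2o_ppbv)
  rf_n2o <- rf_of(base$rf, "N2O") +
    (n2o_traj$concentration$values - base$n2o_ppbv) * s$s_n2o

  # CH4 box continued from 2019; lifetime responds to the scaled NOx total
  nox_total <- base$nox_ff * f$FF_NOx + base$nox_soil * f$soil_NOx
  nox_2019 <- base$nox_ff + base$nox_soil
  de_nox <- annual_series(2019L, base$de_nox + (nox_total - nox_2019),
                          "Tg yr-1")
  ch4_traj <- ch4_integrate(
    emissions_total = annual_series(2019L, const(base$ch4_emissions_total),
                                    "Tg yr-1"),
    dE_nox = de_nox,
    dE_co = annual_series(2019L, const(base$de_co), "Tg yr-1"),
    dE_voc = annual_series(2019L, const(base$de_voc), "Tg yr-1"),
    dT = annual_series(2019L, const(base$dt_2019), "K"),
    p = p, init_ppb = base$ch4_ppb
  )
  rf_ch4 <- rf_of(base$rf, "CH4") +
    (ch4_traj$concentration$values - base$ch4_ppb) * s$s_ch4

  # Aerosols and O3 scale with precursor emission ratios (livestock NH3
  # follows the manure factor: it is a manure-management emission)
  nh3_total <- base$nh3_ff * f$FF_NH3 + base$nh3_soil * f$soil_NH3 +
    base$nh3_livestock * f$manure
  nh3_2019 <- base$nh3_ff + base$nh3_soil + base$nh3_livestock
  rf_aer <- rf_of(base$rf, "aerosols") *
    (nox_total + nh3_total) / (nox_2019 + nh3_2019)
  rf_o3 <- rf_of(base$rf, "O3") * nox_total / nox_2019

  central <- list(CO2 = rf_co2, N2O = rf_n2o, CH4 = rf_ch4,
                  aerosols = rf_aer, O3 = rf_o3)
  central$net <- Reduce(`+`, central[FORCING_AGENTS])

  rows <- lapply(names(central), function(ag) {
    cc <- central[[ag]]
    if (uncertainty && ag != "net") {
      c0 <- rf_of(base$rf, ag)
      lo <- cc * rf_of(base$rf, ag, "low") / c0
      hi <- cc * rf_of(base$rf, ag, "high") / c0
    } else {
      lo <- hi <- cc
    }
    data.frame(year = years, agent = ag, central = cc, low = lo, high = hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (uncertainty) {
    # net bounds add positionally across agents, per the historical
    # convention
    agsub <- out[out$agent != "net", ]
    lo <- stats::aggregate(low ~ year, agsub, sum)
    hi <- stats::aggregate(high ~ year, agsub, sum)
    out$low[out$agent == "net"] <- lo$low[match(years, lo$year)]
    out$high[out$agent == "net"] <- hi$high[match(years, hi$year)]
  }
  rownames(out) <- NULL
  structure(out, class = c("nr_projection", "data.frame"),
            scenario_id = spec$scenario_id,
            trajectories = list(N2O = n2o_traj, CH4 = ch4_traj))
}

#' Forcing change relative to 2019
#'
#' @param projection An `nr_projection` from [project_forcing()].
#' @return A data frame `year`, `agent`, `delta` (W m-2): each agent's
#'   central forcing minus its 2019 value.
#' @export
delta_vs_2019 <- function(projection) {
  stopifnot(is.data.frame(projection),
            all(c("year", "agent", "central") %in% names(projection)))
  if (!2019 %in% projection$year)
    stop("projection must include the 2019 anchor", call. = FALSE)
  anchor <- projection[projection$year == 2019, c("agent", "central")]
  delta <- projection$central -
    anchor$central[match(projection$agent, anchor$agent)]
  data.frame(year = projection$year, agent = projection$agent,
             delta = delta, stringsAsFactors = FALSE)
}
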