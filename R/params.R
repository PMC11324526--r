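# Box-model constants and radiative sensitivities.

#' Box-model parameter set
#'
#' All constants of the three one-box atmospheric models, with the study's
#' defaults: the airborne partitioning constant alpha and the PgC-to-ppmv
#' conversion for CO2; the mass-to-mixing-ratio conversion and 116-yr
#' perturbation lifetime for N2O; and the CH4 box constants including the
#' OH-lifetime sensitivities to CH4 self-feedback, NOx/CO/VOC emission
#' changes and temperature, the non-OH loss lifetimes, and the 230 Tg yr-1
#' natural CH4 source.
#'
#' @param alpha Airborne fraction of a land-carbon perturbation remaining in
#'   the atmosphere after ocean exchange (dimensionless, default 0.61; see
#'   [airborne_fraction()] for the full-precision derivation 235/385).
#' @param delta_co2 PgC per ppmv CO2 (2.12).
#' @param delta_n2o TgN per ppbv N2O (4.8).
#' @param tau_n2o Perturbation lifetime of atmospheric N2O in years (116).
#' @param delta_ch4 Tg CH4 per ppb (2.78).
#' @param tau_oh0 Reference CH4 lifetime against OH oxidation, years (11.17).
#' @param ch4_ref Reference CH4 concentration in ppb (1783.36, year 2005).
#' @param ref_year Reference year for the CH4 lifetime parametrization (2005).
#' @param s_oh CH4 self-feedback exponent on the OH loss (-0.31).
#' @param s_nox OH-loss sensitivity to NOx emission change, (Tg N yr-1)^-1
#'   (0.0042).
#' @param s_co OH-loss sensitivity to CO emission change, (Tg CO yr-1)^-1
#'   (-0.000105).
#' @param s_voc OH-loss sensitivity to VOC emission change, (Tg VOC yr-1)^-1
#'   (-0.000315).
#' @param s_t OH-loss sensitivity to global-mean surface temperature change,
#'   K^-1 (0.0316).
#' @param tau_strat CH4 lifetime against stratospheric loss, years (120).
#' @param tau_soil CH4 lifetime against soil uptake, years (150).
#' @param tau_tropcl CH4 lifetime against tropospheric chlorine, years (200).
#' @param ch4_natural Natural CH4 source, Tg yr-1 (230).
#'
#' @return A list of class `gas_box_params`.
#' @export
gas_box_params <- function(alpha = 0.61,
                           delta_co2 = 2.12,
                           delta_n2o = 4.8,
                           tau_n2o = 116,
                           delta_ch4 = 2.78,
                           tau_oh0 = 11.17,
                           ch4_ref = 1783.36,
                           ref_year = 2005L,
                           s_oh = -0.31,
                           s_nox = 0.0042,
                           s_co = -0.000105,
                           s_voc = -0.000315,
                           s_t = 0.0316,
                           tau_strat = 120,
                           tau_soil = 150,
                           tau_tropcl = 200,
                           ch4_natural = 230) {
  p <- list(alpha = alpha, delta_co2 = delta_co2, delta_n2o = delta_n2o,
            tau_n2o = tau_n2o, delta_ch4 = delta_ch4, tau_oh0 = tau_oh0,
            ch4_ref = ch4_ref, ref_year = as.integer(ref_year), s_oh = s_oh,
            s_nox = s_nox, s_co = s_co, s_voc = s_voc, s_t = s_t,
            tau_strat = tau_strat, tau_soil = tau_soil,
            tau_tropcl = tau_tropcl, ch4_natural = ch4_natural)
  with(p, {
    stopifnot(tau_n2o > 0, tau_oh0 > 0, tau_strat > 0, tau_soil > 0,
              tau_tropcl > 0, delta_co2 > 0, delta_n2o > 0, delta_ch4 > 0,
              alpha >= 0, alpha <= 1, ch4_ref > 0)
  })
  structure(p, class = "gas_box_params")
}

#' Airborne partitioning constant from a carbon-budget split
#'
#' Fraction of a carbon perturbation remaining airborne given the historical
#' (1850-2019) carbon increases in the atmosphere and the ocean; the default
#' budget figures (235 and 150 PgC) give 0.61 at two decimals.
#'
#' @param atmosphere_pgc Historical atmospheric carbon increase, PgC.
#' @param ocean_pgc Historical oceanic carbon increase, PgC.
#' @return Dimensionless airborne fraction in (0, 1).
#' @examples
#' airborne_fraction()            # 235 / (235 + 150)
#' round(airborne_fraction(), 2)  # 0.61
#' @export
airborne_fraction <- function(atmosphere_pgc = 235, ocean_pgc = 150) {
  stopifnot(atmosphere_pgc > 0, ocean_pgc >= 0)
  atmosphere_pgc / (atmosphere_pgc + ocean_pgc)
}

#' Radiative sensitivities of forcing to greenhouse-gas concentrations
#'
#' Linear sensitivities mapping a concentration change to a direct radiative
#' forcing.  The true values used in the source framework were diagnosed
#' from chemical-transport sensitivity experiments and are not reproduced
#' here; the defaults are illustrative magnitudes from standard simplified
#' forcing expressions and are intended as placeholders that users replace
#' with their own diagnosed values.
#'
#' @param s_co2 W m-2 per ppmv CO2 (illustrative default 0.013).
#' @param s_n2o W m-2 per ppbv N2O (illustrative default 0.003).
#' @param s_ch4 W m-2 per ppb CH4 (illustrative default 0.00036).
#' @return A list of class `sensitivity_constants`.
#' @export
sensitivity_constants <- function(s_co2 = 0.013,
                                  s_n2o = 0.003,
                                  s_ch4 = 0.00036) {
  stopifnot(is.finite(s_co2), is.finite(s_n2o), is.finite(s_ch4),
            s_co2 > 0, s_n2o > 0, s_ch4 > 0)
  structure(list(s_co2 = s_co2, s_n2o = s_n2o, s_ch4 = s_ch4),
            class = "sensitivity_constants")
}
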