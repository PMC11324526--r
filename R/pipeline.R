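# End-to-end orchestration: synthesize or load inputs, attribute drivers,
# run the box models with and without anthropogenic Nr, aggregate forcings,
# and (optionally) project scenarios.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    n_models = 8L,
    start_year = 1850L,
    end_year = 2019L,
    inventory_path = NULL,     # CSV; default: synthetic inventory
    components = NULL,         # forcing_components passthrough; default:
                               # the diagnosed 2019 per-agent forcings
    split = list(agricultural = -0.19, nonagricultural = -0.19),
    unmasking = list(full = 0.11, adjusted = 0.07),
    bb_ch4 = 30,               # biomass-burning CH4, Tg yr-1, held constant
    scenarios = "archetypes",  # or NULL to stop after the historical stages
    horizon_year = 2060,
    dt_2019 = 0.45
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full attribution-to-forcing pipeline
#'
#' Executes the stage order of the analysis: (1) synthesize (or read) the
#' sectoral inventory and generate the factorial ensemble, (2) attribute
#' driver contributions and assemble anthropogenic emission totals
#' (including the soil/livestock NH3 rescaling), (3) run the CO2, N2O and
#' CH4 box models with and without anthropogenic Nr, (4) aggregate
#' per-agent forcings into the net estimate with bounds and record the
#' source-split and unmasking bookkeeping, and (5) project the archetype
#' (or supplied) scenarios.  Every stage failure aborts with the stage name
#' and cause; with `scenarios = NULL` the report stops after the historical
#' stages and is marked partial.
#'
#' @param config Named list overriding the defaults (`seed`, `n_models`,
#'   `start_year`, `end_year`, `inventory_path`, `components`, `split`,
#'   `unmasking`, `bb_ch4`, `scenarios`, `horizon_year`, `dt_2019`), or a
#'   path to a YAML file holding such a list.
#' @param params A [gas_box_params()] set.
#' @param sens A [sensitivity_constants()] set (used for the reported
#'   concentration-derived greenhouse-gas forcings; the headline net uses
#'   the passthrough components).
#' @return A report list (class `nrforce_report`) with elements `seed`,
#'   `emissions`, `attribution`, `concentrations`, `forcing`, `split`,
#'   `unmasking`, `projections` and `partial`.
#' @export
run_pipeline <- function(config = list(), params = gas_box_params(),
                         sens = sensitivity_constants()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  fc <- fixture_config(seed = cfg$seed, n_models = cfg$n_models,
                       start_year = cfg$start_year, end_year = cfg$end_year)
  design <- default_experiment_design()

  inputs <- run_stage("inputs", {
    inventory <- if (is.null(cfg$inventory_path)) generate_inventory(fc)
                 else read_inventory_csv(cfg$inventory_path)
    list(inventory = inventory,
         runs = generate_ensemble(fc, design),
         temperature = generate_temperature(fc, dt_2019 = cfg$dt_2019))
  })

  attrib <- run_stage("attribution", {
    at <- attribute_drivers(inputs$runs, design)
    nbp <- anthropogenic_nr_soil_flux(at, "NBP")
    n2o_soil <- anthropogenic_nr_soil_flux(at, "soilN2O")
    nox_soil <- anthropogenic_nr_soil_flux(at, "soilNOx")
    agri_nh3_2019 <- series_value(
      inventory_series(inputs$inventory, "NH3-N", "agriculture"), 2019L)
    nh3 <- scale_soil_nh3(agri_nh3_2019,
                          anthropogenic_nr_soil_flux(at, "soilNH3")$mean)
    list(set = at, nbp = nbp, n2o_soil = n2o_soil, nox_soil = nox_soil,
         nh3 = nh3)
  })

  totals <- run_stage("totals", {
    nox <- total_anthropogenic_emissions(inputs$inventory, "NOx-N",
                                         attrib$nox_soil$mean)
    nh3 <- total_anthropogenic_emissions(
      inputs$inventory, "NH3-N", list(attrib$nh3$soil, attrib$nh3$livestock))
    list(nox = nox, nh3 = nh3)
  })

  boxes <- run_stage("box_models", {
    at <- attrib$set
    co2 <- co2_perturbation(get_attribution(at, "NBP", "fertilizer")$mean,
                            get_attribution(at, "NBP", "manure")$mean,
                            get_attribution(at, "NBP", "Ndep")$mean, params)
    natural_soil <- get_attribution(at, "soilN2O", "natural")$mean
    ff_n2o <- inventory_series(inputs$inventory, "N2O-N",
                               setdiff(INVENTORY_SECTORS, "agriculture"))
    years <- series_years(ff_n2o)
    const <- function(v) annual_series(years[1L], rep(v, length(years)),
                                       "TgN yr-1")
    src_with <- n2o_sources(FF = ff_n2o,
                            soil = natural_soil + attrib$n2o_soil$mean,
                            BB = const(0.7), AREC = const(0.4),
                            chem = const(0.4), NREC = const(0.3),
                            ocean = const(3.4))
    src_wo <- n2o_sources(FF = ff_n2o * 0, soil = natural_soil,
                          BB = const(0.7), AREC = const(0), chem = const(0.4),
                          NREC = const(0.3), ocean = const(3.4))
    init <- params$tau_n2o * sum(vapply(src_wo, function(s) s$values[1L],
                                        0)) / params$delta_n2o
    n2o_with <- n2o_integrate(src_with, params, init_ppbv = init)
    n2o_wo <- n2o_integrate(src_wo, params, init_ppbv = init)

    e_ch4 <- annual_series(
      years[1L],
      inventory_series(inputs$inventory, "CH4")$values + cfg$bb_ch4 +
        params$ch4_natural, "Tg yr-1")
    de_of <- function(x) annual_series(
      years[1L], x$values - series_value(x, params$ref_year), "Tg yr-1")
    de_nox_with <- de_of(totals$nox)
    de_nox_wo <- annual_series(
      years[1L],
      rep(totals$nox$values[1L] - series_value(totals$nox, params$ref_year),
          length(years)), "Tg yr-1")
    de_co <- de_of(inventory_series(inputs$inventory, "CO"))
    de_voc <- de_of(inventory_series(inputs$inventory, "VOC"))
    ch4_with <- ch4_integrate(e_ch4, de_nox_with, de_co, de_voc,
                              inputs$temperature, params)
    ch4_wo <- ch4_integrate(e_ch4, de_nox_wo, de_co, de_voc,
                            inputs$temperature, params)
    list(co2 = co2, n2o_with = n2o_with, n2o_without = n2o_wo,
         ch4_with = ch4_with, ch4_without = ch4_wo,
         dn2o = nr_concentration_effect(n2o_with, n2o_wo),
         dch4 = nr_concentration_effect(ch4_with, ch4_wo))
  })

  forcing <- run_stage("forcing", {
    components <- if (is.null(cfg$components)) historical_forcing_2019()
                  else cfg$components
    if (is.character(components)) components <- read_components_csv(components)
    net <- aggregate_net(components)
    ghg_from_conc <- list(
      CO2 = series_value(concentration_to_forcing(
        boxes$co2$concentration, "CO2", sens), 2019L),
      N2O = series_value(concentration_to_forcing(boxes$dn2o, "N2O", sens),
                         2019L),
      CH4 = series_value(concentration_to_forcing(boxes$dch4, "CH4", sens),
                         2019L))
    list(components = as.data.frame(components), net = as.data.frame(net),
         ghg_from_concentrations = ghg_from_conc)
  })

  split <- run_stage("split", {
    sp <- split_nonlinearity(forcing$net$central,
                             cfg$split$agricultural,
                             cfg$split$nonagricultural)
    sp$unmasking <- unmasking_adjustment(cfg$unmasking$full,
                                         cfg$unmasking$adjusted)
    sp
  })

  projections <- if (is.null(cfg$scenarios)) NULL else run_stage(
    "scenarios", {
      specs <- if (identical(cfg$scenarios, "archetypes"))
        generate_scenarios(fc, horizon_year = cfg$horizon_year)
      else cfg$scenarios
      lapply(specs, function(sc)
        as.data.frame(project_forcing(sc, baseline_2019(), params, sens,
                                      horizon_year = cfg$horizon_year)))
    })

  epoch_mean <- function(x) series_mean(x, 2016L, 2019L)
  report <- list(
    seed = cfg$seed,
    partial = is.null(projections),
    emissions = list(
      nox_anthropogenic_2016_2019 = epoch_mean(totals$nox),
      nh3_total_2019 = series_value(totals$nh3, 2019L)),
    attribution = list(
      nbp_anthropogenic_nr = epoch_mean(attrib$nbp$mean),
      nbp_sd = epoch_mean(attrib$nbp$sd),
      soil_n2o_anthropogenic = epoch_mean(attrib$n2o_soil$mean),
      soil_nox_anthropogenic = epoch_mean(attrib$nox_soil$mean)),
    concentrations = list(
      dco2_2019_ppmv = series_value(boxes$co2$concentration, 2019L),
      dn2o_2019_ppbv = series_value(boxes$dn2o, 2019L),
      dch4_2019_ppb = series_value(boxes$dch4, 2019L)),
    forcing = forcing,
    split = split,
    projections = projections
  )
  structure(report, class = "nrforce_report", boxes = boxes,
            attribution_set = attrib$set)
}
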