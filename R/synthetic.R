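# Calibrated synthetic inputs: a sectoral emission inventory, a factorial
# terrestrial-model ensemble, scenario scaling factors and a temperature
# anomaly series, so the full pipeline runs with no external downloads.
# Anthropogenic growth is logistic in time (smooth, zero at the
# pre-industrial start); inter-model spread is multiplicative log-normal,
# standardized so the finite-member ensemble reproduces the calibration
# means and 1-SD spreads exactly.

#' Synthetic fixture configuration
#'
#' Calibration targets are present-day (2016-2020 mean, or 2019 level where
#' noted) global fluxes the generators are anchored to: the anthropogenic-Nr
#' NBP gain of 0.55 +- 0.38 PgC yr-1, the soil N2O partition into
#' fertilizer+manure (2.7 +- 0.95), N deposition (0.80 +- 0.22) and natural
#' (6.2 +- 1.6) TgN yr-1, total anthropogenic NOx of 46.5 TgN yr-1 of which
#' 3.1 +- 0.77 is soil, and the 2019 NH3 totals (50.5 TgN yr-1 overall,
#' 38.2 agricultural).
#'
#' @param seed Integer seed; a fixed seed yields byte-identical outputs.
#' @param n_models Ensemble size (default 8; flux-kind availability is
#'   capped at 8/8/6/3 for NBP/soilN2O/soilNH3/soilNOx).
#' @param start_year,end_year Inclusive year range (default 1850-2019).
#' @param spread Generate inter-model spread (default `TRUE`); with
#'   `FALSE` every member equals the ensemble mean.
#' @param targets Named list of calibration targets (see Details); override
#'   individual entries to move the fixture.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_models = 8L, start_year = 1850L,
                           end_year = 2019L, spread = TRUE,
                           targets = list()) {
  defaults <- list(
    nbp_anthro = 0.55, nbp_sd = 0.38,
    n2o_fm = 2.7, n2o_fm_sd = 0.95,
    n2o_ndep = 0.80, n2o_ndep_sd = 0.22,
    n2o_natural = 6.2, n2o_natural_sd = 1.6,
    nox_anthro_total = 46.5,
    soil_nox_anthro = 3.1, soil_nox_sd = 0.77,
    soil_nox_natural = 9.1,
    nh3_total_2019 = 50.5, nh3_agri_2019 = 38.2,
    n2o_ff_2019 = 2.0,
    ch4_anthro_2019 = 360, co_2019 = 900, voc_2019 = 140
  )
  targets <- utils::modifyList(defaults, targets)
  if (any(!vapply(targets, function(x) is.finite(x) && x > 0, TRUE)))
    stop("all calibration targets must be positive and finite",
         call. = FALSE)
  stopifnot(end_year > start_year, start_year <= 2005L, end_year >= 2019L,
            n_models >= 1L)
  structure(list(seed = as.integer(seed), n_models = as.integer(n_models),
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year), spread = isTRUE(spread),
                 targets = targets),
            class = "fixture_config")
}

# Logistic growth anchored to zero at the series start (so pre-industrial
# anthropogenic values vanish by construction).
anchored_logistic <- function(years, mid, width) {
  l <- 1 / (1 + exp(-(years - mid) / width))
  l - l[1L]
}

SECTOR_SHAPE_PARAMS <- list(
  agriculture    = c(mid = 1960, width = 30),
  energy         = c(mid = 1970, width = 18),
  industry       = c(mid = 1965, width = 20),
  residential    = c(mid = 1950, width = 35),
  shipping       = c(mid = 1985, width = 15),
  solvents       = c(mid = 1980, width = 18),
  transportation = c(mid = 1975, width = 15),
  waste          = c(mid = 1970, width = 25)
)

# Relative sector weights (before calibration) per species, non-agricultural
# part; agriculture is anchored separately.
SECTOR_WEIGHTS <- list(
  "NOx-N" = c(energy = 0.25, industry = 0.15, residential = 0.08,
              shipping = 0.09, solvents = 0.01, transportation = 0.37,
              waste = 0.05),
  "NH3-N" = c(energy = 0.10, industry = 0.15, residential = 0.25,
              shipping = 0.02, solvents = 0.03, transportation = 0.15,
              waste = 0.30),
  "N2O-N" = c(energy = 0.30, industry = 0.30, residential = 0.10,
              shipping = 0.03, solvents = 0.02, transportation = 0.15,
              waste = 0.10),
  "CH4"   = c(energy = 0.45, industry = 0.10, residential = 0.10,
              shipping = 0.01, solvents = 0.01, transportation = 0.05,
              waste = 0.28),
  "CO"    = c(energy = 0.15, industry = 0.20, residential = 0.25,
              shipping = 0.03, solvents = 0.02, transportation = 0.30,
              waste = 0.05),
  "VOC"   = c(energy = 0.20, industry = 0.20, residential = 0.10,
              shipping = 0.02, solvents = 0.25, transportation = 0.18,
              waste = 0.05)
)

species_units <- function(species)
  if (species %in% c("NOx-N", "NH3-N", "N2O-N")) "TgN yr-1" else "Tg yr-1"

#' Generate a synthetic sectoral emission inventory
#'
#' Smooth logistic-growth series per species and sector over the configured
#' years, exactly zero at the start year, deterministically calibrated:
#' the non-agricultural NOx sum plus the anthropogenic soil NOx target
#' equals the total anthropogenic NOx target over 2016-2020; the
#' agricultural NH3 emission hits its 2019 anchor and the non-agricultural
#' NH3 sum the remainder of the 2019 total; the non-agricultural N2O sum
#' and the CH4/CO/VOC totals hit their respective anchors.
#'
#' @param cfg A [fixture_config()].
#' @return A long-format inventory data frame (`year`, `species`, `sector`,
#'   `value`, `units`).
#' @export
generate_inventory <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  tg <- cfg$targets
  years <- cfg$start_year:cfg$end_year
  shapes <- vapply(SECTOR_SHAPE_PARAMS, function(pp)
    anchored_logistic(years, pp[["mid"]], pp[["width"]]),
    numeric(length(years)))  # years x sectors

  calib_mean <- function(v) mean(v[years >= 2016 & years <= 2020])
  calib_2019 <- function(v) v[match(2019L, years)]

  # non-agricultural calibration: (species, target, anchor function)
  nonagri_target <- list(
    "NOx-N" = list(tg$nox_anthro_total - tg$soil_nox_anthro, calib_mean),
    "NH3-N" = list(tg$nh3_total_2019 - tg$nh3_agri_2019, calib_2019),
    "N2O-N" = list(tg$n2o_ff_2019, calib_mean),
    "CH4"   = list(tg$ch4_anthro_2019, calib_2019),
    "CO"    = list(tg$co_2019, calib_2019),
    "VOC"   = list(tg$voc_2019, calib_2019)
  )
  # agricultural 2019 anchors (direct field-burning/soils entries for the
  # non-NH3 species are small)
  agri_2019 <- c("NOx-N" = 0.8, "NH3-N" = tg$nh3_agri_2019, "N2O-N" = 0.2,
                 "CH4" = 0, "CO" = 0, "VOC" = 0)

  rows <- list()
  for (sp in NR_SPECIES) {
    w <- SECTOR_WEIGHTS[[sp]]
    raw <- shapes[, names(w), drop = FALSE] %*% w
    tgt <- nonagri_target[[sp]]
    k <- tgt[[1L]] / tgt[[2L]](as.vector(raw))
    for (sec in names(w))
      rows[[paste(sp, sec)]] <- data.frame(
        year = years, species = sp, sector = sec,
        value = k * w[[sec]] * shapes[, sec],
        units = species_units(sp), stringsAsFactors = FALSE)
    agshape <- shapes[, "agriculture"]
    agval <- if (agri_2019[[sp]] > 0)
      agri_2019[[sp]] * agshape / calib_2019(agshape) else agshape * 0
    rows[[paste(sp, "agriculture")]] <- data.frame(
      year = years, species = sp, sector = "agriculture", value = agval,
      units = species_units(sp), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Standardized multiplicative spread: log-normal draws affinely standardized
# to exact sample mean 1 and exact sample SD = ratio, so finite-member
# calibration is exact.  Constant in time.
spread_multipliers <- function(n, ratio) {
  if (n == 1L || ratio == 0) return(rep(1, n))
  l <- exp(stats::rnorm(n, 0, 0.3))
  z <- (l - mean(l)) / stats::sd(l)
  1 + ratio * z
}

# k mutually sample-orthogonal standardized columns (mean 0, SD 1, zero
# sample covariance); requires n - 1 >= k.  With per-driver SDs assigned
# proportionally to the driver means, both the quadrature combination of
# driver SDs and the member-level SD of the summed contribution then hit a
# group SD target exactly.
orthogonal_spread <- function(n, k) {
  stopifnot(n - 1L >= k)
  x <- matrix(exp(stats::rnorm(n * k, 0, 0.3)), n, k)
  xc <- sweep(x, 2L, colMeans(x))
  q <- qr.Q(qr(xc))[, seq_len(k), drop = FALSE]
  apply(q, 2L, function(col) col / stats::sd(col))
}

# Per flux kind: driver effect levels at the calibration epoch (2016-2020
# mean), spread groups, and the natural baseline.  A group is either
# "orthogonal" (per-driver multipliers with zero sample covariance and SDs
# proportional to the driver means, so quadrature and member-sum SD both
# equal `sd_target` exactly) or "shared" (one multiplier for the whole
# group; `sd_target` is the member-sum SD, or `rel` a plain relative
# spread).
ensemble_recipe <- function(tg) {
  list(
    NBP = list(
      units = "PgC yr-1",
      effects = c(fertilizer = tg$nbp_anthro * 6 / 11,
                  manure = tg$nbp_anthro * 3 / 11,
                  Ndep = tg$nbp_anthro * 2 / 11,
                  irrigation = 0.05, CO2 = 0.8, climate = -0.2,
                  LUC = -1.2),
      groups = list(
        anthro = list(drivers = c("fertilizer", "manure", "Ndep"),
                      mode = "orthogonal", sd_target = tg$nbp_sd),
        other = list(drivers = c("irrigation", "CO2", "climate", "LUC"),
                     mode = "shared", rel = 0.3)),
      natural = 0, natural_ratio = 0, noise_sd = 0.05),
    soilN2O = list(
      units = "TgN yr-1",
      effects = c(fertilizer = tg$n2o_fm * 2 / 3,
                  manure = tg$n2o_fm * 1 / 3,
                  Ndep = tg$n2o_ndep,
                  irrigation = 0.05, CO2 = 0.15, climate = 0.2,
                  LUC = -0.1),
      groups = list(
        fm = list(drivers = c("fertilizer", "manure"),
                  mode = "orthogonal", sd_target = tg$n2o_fm_sd),
        ndep = list(drivers = "Ndep", mode = "orthogonal",
                    sd_target = tg$n2o_ndep_sd),
        other = list(drivers = c("irrigation", "CO2", "climate", "LUC"),
                     mode = "shared", rel = 0.3)),
      natural = tg$n2o_natural,
      natural_ratio = tg$n2o_natural_sd / tg$n2o_natural, noise_sd = 0.01),
    soilNOx = list(
      units = "TgN yr-1",
      effects = c(fertilizer = tg$soil_nox_anthro * 0.55,
                  manure = tg$soil_nox_anthro * 0.29,
                  Ndep = tg$soil_nox_anthro * 0.16,
                  irrigation = 0.02, CO2 = 0.1, climate = 0.15,
                  LUC = -0.05),
      groups = list(
        anthro = list(drivers = c("fertilizer", "manure", "Ndep"),
                      mode = "shared", sd_target = tg$soil_nox_sd),
        other = list(drivers = c("irrigation", "CO2", "climate", "LUC"),
                     mode = "shared", rel = 0.3)),
      natural = tg$soil_nox_natural, natural_ratio = 0.28, noise_sd = 0.01),
    soilNH3 = list(
      units = "TgN yr-1",
      effects = c(fertilizer = 20, manure = 12, Ndep = 2,
                  irrigation = 0.1, CO2 = 0.5, climate = 0.5, LUC = -0.3),
      groups = list(
        anthro = list(drivers = c("fertilizer", "manure", "Ndep"),
                      mode = "shared", rel = 0.35),
        other = list(drivers = c("irrigation", "CO2", "climate", "LUC"),
                     mode = "shared", rel = 0.3)),
      natural = 5, natural_ratio = 0.3, noise_sd = 0.01)
  )
}

DRIVER_SHAPE_PARAMS <- list(
  fertilizer = c(mid = 1980, width = 14),
  manure     = c(mid = 1965, width = 22),
  Ndep       = c(mid = 1970, width = 18),
  irrigation = c(mid = 1960, width = 25),
  CO2        = c(mid = 1985, width = 20),
  climate    = c(mid = 1990, width = 18),
  LUC        = c(mid = 1940, width = 40)
)

# Experiments generated: SH1/SH12 all drivers on, SH2..SH8 single factor
# off, SH9 all off, SH11 all on except LUC.
EXPERIMENT_TABLE <- list(
  SH1  = NULL,          # all on (NULL = nothing switched off)
  SH2  = "fertilizer",
  SH3  = "manure",
  SH4  = "Ndep",
  SH5  = "irrigation",
  SH7  = "CO2",
  SH8  = "climate",
  SH9  = c("fertilizer", "manure", "Ndep", "irrigation", "CO2", "climate",
           "LUC"),
  SH11 = "LUC",
  SH12 = NULL
)

FLUX_AVAILABILITY <- c(NBP = 8L, soilN2O = 8L, soilNH3 = 6L, soilNOx = 3L)

#' Generate a synthetic factorial terrestrial-model ensemble
#'
#' Per-model driver effects are constructed additively (each experiment is
#' the model's natural baseline plus the effects of the drivers switched
#' on), so factorial differencing recovers the injected effects exactly.
#' Inter-model spread is multiplicative log-normal, standardized so the
#' ensemble mean and 1-SD spread of each calibrated group hit their targets
#' exactly at the 2016-2020 epoch; a model's interannual noise lives in its
#' natural baseline and is identical across its experiments.  Flux-kind
#' availability mirrors the source ensemble: 8 members for NBP and soil
#' N2O, 6 for soil NH3, 3 for soil NOx.
#'
#' @param cfg A [fixture_config()] (with `spread = FALSE`, `n_models = 1`
#'   is allowed; otherwise at least 2 members are required).
#' @param design An [experiment_design()]; experiments referenced by the
#'   design must be in the generated table (SH1-SH5, SH7-SH9, SH11, SH12).
#' @return A list of [factorial_run()] objects.
#' @export
generate_ensemble <- function(cfg = fixture_config(),
                              design = default_experiment_design()) {
  stopifnot(inherits(cfg, "fixture_config"),
            inherits(design, "experiment_design"))
  if (cfg$spread && cfg$n_models < 2L)
    stop("n_models must be at least 2 when spread is enabled", call. = FALSE)
  wanted <- unique(c(unlist(design$driver_rules), design$natural_experiment))
  missing <- setdiff(wanted, names(EXPERIMENT_TABLE))
  if (length(missing))
    stop("design references experiments not generated: ",
         paste(missing, collapse = ", "), call. = FALSE)
  set.seed(cfg$seed)
  years <- cfg$start_year:cfg$end_year
  ny <- length(years)
  epoch <- years >= 2016 & years <= 2020
  recipe <- ensemble_recipe(cfg$targets)
  runs <- list()
  for (fk in names(recipe)) {
    rc <- recipe[[fk]]
    nm <- min(cfg$n_models, FLUX_AVAILABILITY[[fk]])
    models <- paste0("M", seq_len(nm))
    # effect trajectories, normalized to the 2016-2020 epoch level
    eff <- lapply(names(rc$effects), function(d) {
      pp <- DRIVER_SHAPE_PARAMS[[d]]
      sh <- anchored_logistic(years, pp[["mid"]], pp[["width"]])
      rc$effects[[d]] * sh / mean(sh[epoch])
    })
    names(eff) <- names(rc$effects)
    # per-group standardized multipliers
    mult <- matrix(1, nrow = nm, ncol = length(rc$effects),
                   dimnames = list(models, names(rc$effects)))
    if (cfg$spread)
      for (g in rc$groups) {
        mus <- vapply(g$drivers, function(d) rc$effects[[d]], 0)
        if (identical(g$mode, "orthogonal") && nm - 1L >= length(g$drivers)) {
          z <- orthogonal_spread(nm, length(g$drivers))
          r <- g$sd_target / sqrt(sum(mus^2))
          for (j in seq_along(g$drivers))
            mult[, g$drivers[j]] <- 1 + r * z[, j]
        } else {
          ratio <- if (!is.null(g$sd_target)) g$sd_target / abs(sum(mus))
                   else g$rel
          m <- spread_multipliers(nm, ratio)
          for (d in g$drivers) mult[, d] <- m
        }
      }
    nat_mult <- if (cfg$spread) spread_multipliers(nm, rc$natural_ratio)
                else rep(1, nm)
    for (i in seq_len(nm)) {
      noise <- if (cfg$spread) stats::rnorm(ny, 0, rc$noise_sd) else
        numeric(ny)
      natural <- rc$natural * nat_mult[i] + noise
      for (ex in names(EXPERIMENT_TABLE)) {
        off <- EXPERIMENT_TABLE[[ex]]
        on <- setdiff(names(rc$effects), off)
        v <- natural
        for (d in on) v <- v + eff[[d]] * mult[i, d]
        runs[[paste(fk, models[i], ex, sep = ".")]] <- factorial_run(
          models[i], ex, fk, annual_series(cfg$start_year, v, rc$units))
      }
    }
  }
  unname(runs)
}

#' Generate archetype scenario scaling factors
#'
#' Three illustrative archetypes over 2019-`horizon_year`, all anchored at
#' exactly 1 in 2019: `"cleaner"` (fossil NOx declining steeply to a small
#' fraction by 2050, fertilizer/manure roughly flat), `"fertilizer_growth"`
#' (fossil sources flat, fertilizer and manure rising monotonically) and
#' `"flat"` (all factors 1).  These emulate the qualitative behaviour of
#' strong-mitigation, regional-rivalry and fossil-intensive pathway
#' families; they are illustrative shapes, not the pathway datasets.
#'
#' @param cfg A [fixture_config()] (only carried for provenance; the
#'   factors are deterministic).
#' @param horizon_year Last scenario year (default 2060).
#' @return A named list of three [scenario_spec()] objects.
#' @export
generate_scenarios <- function(cfg = fixture_config(), horizon_year = 2060) {
  years <- 2019:horizon_year
  ramp <- function(to, by_year = 2050) {
    v <- 1 + (to - 1) * pmin(pmax(years - 2019, 0) / (by_year - 2019), 1)
    annual_series(2019L, v, "1")
  }
  flat <- ramp(1)
  composite <- function(fert, man, ndep)
    annual_series(2019L, 0.5 * fert$values + 0.3 * man$values +
                    0.2 * ndep$values, "1")
  mk <- function(id, fert, man, ndep, ff_nox, ff_nh3) {
    soil <- composite(fert, man, ndep)
    scenario_spec(id, list(
      fertilizer = fert, manure = man, Ndep = ndep,
      FF_NOx = ff_nox, FF_N2O = ff_nox, FF_NH3 = ff_nh3,
      soil_NOx = soil, soil_NH3 = soil, soil_N2O = soil))
  }
  list(
    cleaner = mk("cleaner", fert = flat, man = flat, ndep = ramp(0.6),
                 ff_nox = ramp(0.2), ff_nh3 = ramp(0.7)),
    fertilizer_growth = mk("fertilizer_growth", fert = ramp(1.5),
                           man = ramp(1.4), ndep = flat, ff_nox = flat,
                           ff_nh3 = flat),
    flat = mk("flat", fert = flat, man = flat, ndep = flat, ff_nox = flat,
              ff_nh3 = flat)
  )
}

#' Generate a synthetic global temperature anomaly
#'
#' A smooth warming trajectory expressed as the departure of global-mean
#' surface temperature from the 2005 CH4-lifetime reference year: exactly 0
#' in 2005, monotone increasing, reaching `dt_2019` K by 2019.
#'
#' @param cfg A [fixture_config()].
#' @param dt_2019 Anomaly in 2019 relative to 2005, K (default 0.45).
#' @return An [annual_series()] in K.
#' @export
generate_temperature <- function(cfg = fixture_config(), dt_2019 = 0.45) {
  years <- cfg$start_year:cfg$end_year
  w <- 1 / (1 + exp(-(years - 1990) / 25))
  w2005 <- 1 / (1 + exp(-(2005 - 1990) / 25))
  w2019 <- 1 / (1 + exp(-(2019 - 1990) / 25))
  annual_series(cfg$start_year, dt_2019 * (w - w2005) / (w2019 - w2005), "K")
}
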