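test_that("factorial differencing recovers injected additive effects", {
  effects <- list(
    M1 = c(fertilizer = 1.0, manure = 0.5, Ndep = 0.25),
    M2 = c(fertilizer = 1.0, manure = 0.7, Ndep = 0.15)
  )
  at <- attribute_drivers(tiny_runs(effects), tiny_design())
  fert <- get_attribution(at, "soilN2O", "fertilizer")
  expect_equal(fert$mean$values, rep(1.0, 5))
  expect_equal(fert$sd$values, rep(0, 5))
  man <- get_attribution(at, "soilN2O", "manure")
  expect_equal(man$mean$values, rep(0.6, 5))
  expect_equal(man$sd$values, rep(stats::sd(c(0.5, 0.7)), 5))
  nat <- get_attribution(at, "soilN2O", "natural")
  expect_equal(nat$mean$values, rep(5, 5))
})

test_that("ensemble statistics use the sample-SD convention", {
  effects <- list(M1 = c(fertilizer = 2), M2 = c(fertilizer = 3),
                  M3 = c(fertilizer = 4))
  at <- attribute_drivers(tiny_runs(effects), tiny_design("fertilizer"))
  fert <- get_attribution(at, "soilN2O", "fertilizer")
  expect_equal(fert$mean$values, rep(3, 5))
  expect_equal(fert$sd$values, rep(1, 5))  # sd(c(2,3,4)) with n-1
  expect_equal(fert$n_models, 3L)
})

test_that("attribution is invariant to run ordering and handles gaps", {
  effects <- list(M1 = c(fertilizer = 1, manure = 2),
                  M2 = c(fertilizer = 3, manure = 1))
  runs <- tiny_runs(effects)
  at1 <- attribute_drivers(runs, tiny_design(c("fertilizer", "manure")))
  at2 <- attribute_drivers(rev(runs), tiny_design(c("fertilizer", "manure")))
  expect_equal(at1[["soilN2O.fertilizer"]]$mean$values,
               at2[["soilN2O.fertilizer"]]$mean$values)
  # drop one of M2's experiments: M2 is excluded from that driver only
  drop <- !(vapply(runs, function(r)
    r$model_id == "M2" && r$experiment_id == "OFF_fertilizer", TRUE))
  expect_warning(
    at3 <- attribute_drivers(runs[drop],
                             tiny_design(c("fertilizer", "manure"))),
    "lacks experiment pair")
  expect_equal(at3[["soilN2O.fertilizer"]]$n_models, 1L)
  expect_equal(at3[["soilN2O.fertilizer"]]$mean$values, rep(1, 5))
  expect_equal(at3[["soilN2O.manure"]]$n_models, 2L)
  # removing all models for a pair is an error
  only_m1 <- Filter(function(r) r$model_id == "M1", runs)
  no_off <- Filter(function(r) r$experiment_id != "OFF_fertilizer", only_m1)
  expect_error(suppressWarnings(
    attribute_drivers(no_off, tiny_design("fertilizer"))), "empty ensemble")
})

test_that("driver contributions close the full-minus-off budget", {
  effects <- list(M1 = c(fertilizer = 1.2, manure = 0.4, Ndep = 0.1),
                  M2 = c(fertilizer = 0.8, manure = 0.6, Ndep = 0.3))
  runs <- tiny_runs(effects)
  at <- attribute_drivers(runs, tiny_design())
  total_attr <- series_sum(lapply(c("fertilizer", "manure", "Ndep"),
                                  function(d)
                                    get_attribution(at, "soilN2O", d)$mean))
  sh1 <- Filter(function(r) r$experiment_id == "SH1", runs)
  sh9 <- Filter(function(r) r$experiment_id == "SH9", runs)
  full_minus_off <- (sh1[[1L]]$series + sh1[[2L]]$series) / 2 -
    (sh9[[1L]]$series + sh9[[2L]]$series) / 2
  expect_equal(total_attr$values, full_minus_off$values, tolerance = 1e-12)
})

test_that("anthropogenic Nr soil flux sums the three direct drivers", {
  effects <- list(M1 = c(fertilizer = 1.0, manure = 2.0, Ndep = 0.5),
                  M2 = c(fertilizer = 1.0, manure = 2.0, Ndep = 0.5))
  at <- attribute_drivers(tiny_runs(effects), tiny_design())
  nr <- anthropogenic_nr_soil_flux(at, "soilN2O")
  expect_equal(nr$mean$values, rep(3.5, 5))
  expect_equal(nr$sd$values, rep(0, 5))
  # all-zero drivers give a zero series
  zero <- list(M1 = c(fertilizer = 0, manure = 0, Ndep = 0),
               M2 = c(fertilizer = 0, manure = 0, Ndep = 0))
  at0 <- attribute_drivers(tiny_runs(zero), tiny_design())
  expect_equal(anthropogenic_nr_soil_flux(at0, "soilN2O")$mean$values,
               rep(0, 5))
  # spreads combine in quadrature within one flux
  spread <- list(M1 = c(fertilizer = 1, manure = 2, Ndep = 1),
                 M2 = c(fertilizer = 3, manure = 4, Ndep = 2))
  ats <- attribute_drivers(tiny_runs(spread), tiny_design())
  nrs <- anthropogenic_nr_soil_flux(ats, "soilN2O")
  expect_equal(nrs$sd$values,
               rep(sqrt(sd(c(1, 3))^2 + sd(c(2, 4))^2 + sd(c(1, 2))^2), 5))
})

test_that("NH3 rescaling anchors 2019 and is homogeneous in the anchor", {
  shape <- annual_series(2015, c(20, 25, 30, 35, 40), "TgN yr-1")
  out <- scale_soil_nh3(38.2, shape)
  expect_equal(series_value(out$soil, 2019), 0.48 * 38.2)  # 18.336
  expect_equal(series_value(out$livestock, 2019), 0.52 * 38.2)
  expect_equal(series_value(out$total, 2019), 38.2)
  # degree-1 homogeneity in the anchor
  out2 <- scale_soil_nh3(2 * 38.2, shape)
  expect_equal(out2$soil$values, 2 * out$soil$values)
  # a flat ensemble shape yields a flat scaled series
  flat <- scale_soil_nh3(10, const_series(7, n = 6, start = 2014L))
  expect_equal(flat$soil$values, rep(4.8, 6))
  expect_error(scale_soil_nh3(38.2, annual_series(2018, c(1, 0), "TgN yr-1")),
               "zero 2019")
  expect_error(scale_soil_nh3(0, shape), "positive")
})

test_that("species totals add fossil sectors and soil, never agriculture", {
  inv <- rbind(
    data.frame(year = 2000:2004, species = "NOx-N", sector = "energy",
               value = 10, units = "TgN yr-1"),
    data.frame(year = 2000:2004, species = "NOx-N", sector = "transportation",
               value = 5, units = "TgN yr-1"),
    data.frame(year = 2000:2004, species = "NOx-N", sector = "agriculture",
               value = 99, units = "TgN yr-1")
  )
  soil <- const_series(2, start = 2000L)
  tot <- total_anthropogenic_emissions(inv, "NOx-N", soil)
  expect_equal(tot$values, rep(17, 5))  # 10 + 5 + 2; agriculture excluded
  expect_equal(total_anthropogenic_emissions(inv, "NOx-N")$values,
               rep(15, 5))
  expect_error(total_anthropogenic_emissions(inv, "NH3-N"),
               "'NH3-N' absent")
})

test_that("NH3 total re-derives from its components without double counting", {
  fc <- fixture_config(seed = 11)
  inv <- generate_inventory(fc)
  at <- attribute_drivers(generate_ensemble(fc))
  agri <- series_value(inventory_series(inv, "NH3-N", "agriculture"), 2019)
  parts <- scale_soil_nh3(agri, anthropogenic_nr_soil_flux(at, "soilNH3")$mean)
  total <- total_anthropogenic_emissions(inv, "NH3-N",
                                         list(parts$soil, parts$livestock))
  fossil <- inventory_series(inv, "NH3-N",
                             setdiff(unique(inv$sector), "agriculture"))
  rebuilt <- fossil$values + 0.48 * agri * parts$soil$values /
    series_value(parts$soil, 2019) + 0.52 * agri * parts$livestock$values /
    series_value(parts$livestock, 2019)
  expect_equal(total$values, rebuilt, tolerance = 1e-12)
  expect_equal(series_value(total, 2019), 50.5, tolerance = 1e-8)
})
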