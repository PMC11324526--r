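mk_factor <- function(values, start = 2019L) annual_series(start, values, "1")

# a scenario with every factor constant at `k` from 2020 onward (1 in 2019)
step_scenario <- function(k = 1, horizon = 2030L, overrides = list()) {
  n <- horizon - 2019L + 1L
  f <- mk_factor(c(1, rep(k, n - 1L)))
  factors <- stats::setNames(rep(list(f), 9L),
                             c("fertilizer", "manure", "Ndep", "FF_NOx",
                               "FF_N2O", "FF_NH3", "soil_NOx", "soil_NH3",
                               "soil_N2O"))
  for (nm in names(overrides)) factors[[nm]] <- overrides[[nm]]
  scenario_spec(sprintf("step_%g", k), factors)
}

test_that("scenario specs enforce the 2019 anchor and non-negativity", {
  bad <- mk_factor(c(1.1, 1, 1))
  expect_error(step_scenario(1, 2021, list(FF_NOx = bad)),
               "must equal 1.0 in 2019")
  neg <- mk_factor(c(1, -0.1, 1))
  expect_error(step_scenario(1, 2021, list(manure = neg)), "negative")
  spec <- step_scenario(1, 2021)
  expect_error(scenario_spec("x", spec$factors[-1L]), "missing scenario")
})

test_that("all-factors-one leaves emission-ratio forcings at their 2019 values", {
  proj <- project_forcing(step_scenario(1, 2040), horizon_year = 2040)
  aer <- proj[proj$agent == "aerosols", ]
  o3 <- proj[proj$agent == "O3", ]
  expect_equal(aer$central, rep(-0.24, nrow(aer)), tolerance = 1e-12)
  expect_equal(o3$central, rep(0.05, nrow(o3)), tolerance = 1e-12)
})

test_that("aerosol and O3 forcings are homogeneous of degree 1 in emissions", {
  for (k in c(0.5, 1.2, 2)) {
    proj <- project_forcing(step_scenario(k, 2030), horizon_year = 2030)
    aer_2030 <- proj$central[proj$agent == "aerosols" & proj$year == 2030]
    o3_2030 <- proj$central[proj$agent == "O3" & proj$year == 2030]
    expect_equal(aer_2030, k * -0.24, tolerance = 1e-12)
    expect_equal(o3_2030, k * 0.05, tolerance = 1e-12)
  }
  # halved precursors: aerosol forcing -0.12; NOx * 1.2: O3 +0.06
  half <- project_forcing(step_scenario(0.5, 2030), horizon_year = 2030)
  expect_equal(half$central[half$agent == "aerosols" & half$year == 2030],
               -0.12, tolerance = 1e-12)
  up <- project_forcing(step_scenario(1.2, 2030), horizon_year = 2030)
  expect_equal(up$central[up$agent == "O3" & up$year == 2030], 0.06,
               tolerance = 1e-12)
})

test_that("projection is continuous at the 2019 handoff", {
  base <- baseline_2019()
  proj <- project_forcing(step_scenario(0.7, 2035), base,
                          horizon_year = 2035)
  at2019 <- proj[proj$year == 2019, ]
  for (ag in c("CO2", "N2O", "CH4", "aerosols", "O3"))
    expect_equal(at2019$central[at2019$agent == ag],
                 base$rf$central[base$rf$agent == ag], tolerance = 1e-12)
  expect_equal(at2019$central[at2019$agent == "net"], -0.34,
               tolerance = 1e-12)
  traj <- attr(proj, "trajectories")
  expect_equal(series_value(traj$N2O$concentration, 2019), base$n2o_ppbv)
  expect_equal(series_value(traj$CH4$concentration, 2019), base$ch4_ppb)
})

test_that("net projection decomposes into its agents bit-exactly", {
  proj <- project_forcing(step_scenario(0.8, 2045), horizon_year = 2045)
  wide <- split(proj$central, proj$agent)
  recomputed <- wide$CO2 + wide$N2O + wide$CH4 + wide$aerosols + wide$O3
  expect_identical(wide$net, recomputed)
})

test_that("raising only fertilizer never lowers the N2O forcing", {
  lo <- project_forcing(step_scenario(1, 2045), horizon_year = 2045)
  hi_spec <- step_scenario(1, 2045,
                           list(fertilizer = mk_factor(c(1, rep(1.6, 26)))))
  hi <- project_forcing(hi_spec, horizon_year = 2045)
  d <- hi$central[hi$agent == "N2O"] - lo$central[lo$agent == "N2O"]
  expect_true(all(d >= 0))
  expect_gt(d[length(d)], 0)
})

test_that("the saturation ceiling weakens CO2 cooling under N growth", {
  grow <- step_scenario(1, 2045,
                        list(fertilizer = mk_factor(c(1, rep(1.8, 26))),
                             manure = mk_factor(c(1, rep(1.8, 26)))))
  lin <- project_forcing(grow, horizon_year = 2045)
  capped <- project_forcing(grow, horizon_year = 2045, nbp_saturation = 1.2)
  d <- capped$central[capped$agent == "CO2"] -
    lin$central[lin$agent == "CO2"]
  expect_true(all(d >= 0))          # less uptake, weaker cooling
  expect_gt(d[length(d)], 0)
  # ceiling above the factors is inert
  inert <- project_forcing(grow, horizon_year = 2045, nbp_saturation = 5)
  expect_equal(inert$central, lin$central, tolerance = 1e-15)
})

test_that("projection bounds inherit the historical percentage ranges", {
  proj <- project_forcing(step_scenario(1, 2025), horizon_year = 2025)
  aer <- proj[proj$agent == "aerosols" & proj$year == 2025, ]
  expect_equal(aer$low, -0.24 * (-0.18 / -0.24), tolerance = 1e-12)
  expect_equal(aer$high, -0.28, tolerance = 1e-12)
})

test_that("deltas versus 2019 anchor at zero and track the projection", {
  proj <- project_forcing(step_scenario(1, 2030), horizon_year = 2030)
  d <- delta_vs_2019(proj)
  expect_true(all(d$delta[d$year == 2019] == 0))
  expect_true(all(abs(d$delta[d$agent == "aerosols"]) < 1e-12))
  # a projection where aerosols halve gives delta +0.12 at the end
  half <- project_forcing(step_scenario(0.5, 2030), horizon_year = 2030)
  dh <- delta_vs_2019(half)
  expect_equal(dh$delta[dh$agent == "aerosols" & dh$year == 2030], 0.12,
               tolerance = 1e-12)
})
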