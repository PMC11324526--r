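p <- gas_box_params()

zero_n2o_sources <- function(start, end) {
  constant_n2o_sources(
    c(FF = 0, soil = 0, BB = 0, AREC = 0, chem = 0, NREC = 0, ocean = 0),
    start, end)
}

test_that("CO2 perturbation is the scaled cumulative land uptake", {
  n <- 170L
  zero <- annual_series(1850, numeric(n), "PgC yr-1")
  expect_equal(co2_perturbation(zero, zero, zero, p)$concentration$values,
               numeric(n))
  # +1 PgC cumulative uptake lowers CO2 by alpha/delta = 0.61/2.12 ppmv
  unit_nbp <- annual_series(1850, rep(1 / n, n), "PgC yr-1")
  tr <- co2_perturbation(unit_nbp, zero, zero, p)
  expect_equal(series_value(tr$concentration, 1850 + n - 1),
               -0.61 / 2.12, tolerance = 1e-12)
  expect_error(co2_perturbation(annual_series(1850, numeric(n), "TgN yr-1"),
                                zero, zero, p), "PgC yr-1")
})

test_that("CO2 perturbation is exactly linear in each NBP series", {
  set.seed(42)
  n <- 50L
  mk <- function() annual_series(1850, rnorm(n, 0, 0.3), "PgC yr-1")
  zero <- annual_series(1850, numeric(n), "PgC yr-1")
  a <- mk(); b <- mk(); c <- mk()
  together <- co2_perturbation(a, b, c, p)$concentration$values
  separate <- co2_perturbation(a, zero, zero, p)$concentration$values +
    co2_perturbation(zero, b, zero, p)$concentration$values +
    co2_perturbation(zero, zero, c, p)$concentration$values
  expect_equal(together, separate, tolerance = 1e-14)
  doubled <- co2_perturbation(a * 2, b * 2, c * 2, p)$concentration$values
  expect_equal(doubled, 2 * together, tolerance = 1e-15)
})

test_that("constant-source N2O converges to the tau*E/delta steady state", {
  # 12 TgN/yr forever: steady state 116 * 12 / 4.8 = 290 ppbv
  src <- constant_n2o_sources(
    c(FF = 12, soil = 0, BB = 0, AREC = 0, chem = 0, NREC = 0, ocean = 0),
    1850, 1850 + 10 * 116)
  tr <- n2o_integrate(src, p, init_ppbv = 100)
  final <- tr$concentration$values[length(tr$concentration$values)]
  expect_equal(final, 290, tolerance = 1e-3)  # within 0.1% after 10 lifetimes
})

test_that("zero-source N2O decays like the analytic exponential", {
  yrs <- 10 * p$tau_n2o
  src <- zero_n2o_sources(1850, 1850 + yrs)
  expect_warning(tr <- n2o_integrate(src, p, init_ppbv = 270), NA)
  t <- seq_along(tr$concentration$values) - 1
  analytic <- 270 * exp(-t / p$tau_n2o)
  # after 10 lifetimes the Euler decay sits on the closed form to 0.1% of
  # the initial value; over the whole trajectory the annual truncation
  # error stays below 0.2% of it
  n <- length(t)
  expect_lt(abs(tr$concentration$values[n] - analytic[n]) / 270, 1e-3)
  expect_lt(max(abs(tr$concentration$values - analytic)) / 270, 2e-3)
  # a monthly-substep run converges onto the closed form itself
  fine <- n2o_integrate(src, p, init_ppbv = 270, substeps = 12)
  expect_lt(max(abs(fine$concentration$values - analytic) / analytic), 5e-3)
})

test_that("annual Euler N2O matches an independent ODE solver on a ramp", {
  skip_if_not_installed("deSolve")
  n <- 170L
  ramp <- annual_series(1850, seq(10, 15, length.out = n), "TgN yr-1")
  zero <- annual_series(1850, numeric(n), "TgN yr-1")
  src <- n2o_sources(FF = ramp, soil = zero, BB = zero, AREC = zero,
                     chem = zero, NREC = zero, ocean = zero)
  tr <- n2o_integrate(src, p, init_ppbv = 270)
  # oracle: lsoda with the same piecewise-constant annual forcing
  efun <- stats::approxfun(seq_len(n) - 1, ramp$values, method = "constant",
                           rule = 2)
  sol <- deSolve::ode(
    y = c(C = 270), times = seq(0, n - 1),
    func = function(t, y, parms)
      list(efun(t) / p$delta_n2o - y / p$tau_n2o))
  expect_lt(max(abs(tr$concentration$values - sol[, "C"]) / sol[, "C"]),
            5e-3)
})

test_that("N2O concentrations are monotone in every source term", {
  src <- constant_n2o_sources(
    c(FF = 2, soil = 9, BB = 0.7, AREC = 0.4, chem = 0.4, NREC = 0.3,
      ocean = 3.4), 1900, 2000)
  base <- n2o_integrate(src, p, init_ppbv = 280)$concentration$values
  for (cat in c("FF", "soil", "ocean")) {
    bumped <- src
    bumped[[cat]] <- bumped[[cat]] + 1
    up <- n2o_integrate(do.call(n2o_sources, unclass(bumped)), p,
                        init_ppbv = 280)$concentration$values
    expect_true(all(up >= base))
    expect_gt(up[length(up)], base[length(base)])
  }
})

test_that("source inversion recovers the inputs of a synthetic trajectory", {
  n <- 100L
  set.seed(5)
  ramp <- annual_series(1900, 10 + cumsum(rnorm(n, 0.02, 0.05)), "TgN yr-1")
  zero <- annual_series(1900, numeric(n), "TgN yr-1")
  src <- n2o_sources(FF = ramp, soil = zero, BB = zero, AREC = zero,
                     chem = zero, NREC = zero, ocean = zero)
  tr <- n2o_integrate(src, p, init_ppbv = 275)
  recovered <- n2o_implied_sources(tr, p)
  expect_equal(recovered$values, ramp$values[-n], tolerance = 1e-10)
})

test_that("CH4 lifetime composes harmonically and responds to emissions", {
  ref <- ch4_lifetime(p$ch4_ref, p = p)
  expect_equal(ref$tau_oh, 11.17, tolerance = 1e-12)
  harmonic <- 1 / (1 / 11.17 + 1 / 120 + 1 / 150 + 1 / 200)
  expect_equal(ref$tau_ch4, harmonic, tolerance = 1e-12)
  expect_equal(round(ref$tau_ch4, 2), 9.13)
  # +10 Tg N/yr multiplies the OH loss frequency by exp(0.042)
  bump <- ch4_lifetime(p$ch4_ref, dE_nox = 10, p = p)
  expect_equal((1 / bump$tau_oh) / (1 / ref$tau_oh), exp(0.0042 * 10),
               tolerance = 1e-12)
  # with the self-feedback off and no departures, tau_oh is tau_oh0 at any
  # concentration
  p0 <- gas_box_params(s_oh = 0)
  for (c4 in c(900, 1783.36, 2400))
    expect_equal(ch4_lifetime(c4, p = p0)$tau_oh, p0$tau_oh0)
  expect_error(ch4_lifetime(0), "positive")
})

test_that("frozen-lifetime CH4 reaches the closed-form steady state", {
  n <- 120L
  e <- annual_series(1900, rep(556, n), "Tg yr-1")
  zero <- annual_series(1900, numeric(n), "Tg yr-1")
  zk <- annual_series(1900, numeric(n), "K")
  tr <- ch4_integrate(e, zero, zero, zero, zk, p, init_ppb = 1000,
                      fixed_lifetime = 9)
  expect_equal(tr$concentration$values[n], 9 * 556 / p$delta_ch4,
               tolerance = 2e-3)
})

test_that("NOx-driven OH increase lowers CH4 every year after start", {
  n <- 80L
  e <- annual_series(1940, rep(560, n), "Tg yr-1")
  zero <- annual_series(1940, numeric(n), "Tg yr-1")
  zk <- annual_series(1940, numeric(n), "K")
  nox <- annual_series(1940, rep(20, n), "Tg yr-1")
  base <- ch4_integrate(e, zero, zero, zero, zk, p, init_ppb = 1700)
  with_nox <- ch4_integrate(e, nox, zero, zero, zk, p, init_ppb = 1700)
  diff <- nr_concentration_effect(with_nox, base)
  expect_true(all(diff$values[-1L] < 0))
  expect_equal(diff$values[1L], 0)
})

test_that("annual CH4 Euler matches a monthly-substep oracle end to end", {
  fc <- fixture_config(seed = 2)
  inv <- generate_inventory(fc)
  e <- annual_series(1850,
                     inventory_series(inv, "CH4")$values + 30 + 230,
                     "Tg yr-1")
  de <- function(sp) {
    x <- inventory_series(inv, sp)
    annual_series(1850, x$values - series_value(x, 2005), "Tg yr-1")
  }
  nox <- total_anthropogenic_emissions(inv, "NOx-N")
  de_nox <- annual_series(1850, nox$values - series_value(nox, 2005),
                          "Tg yr-1")
  dt <- generate_temperature(fc)
  coarse <- ch4_integrate(e, de_nox, de("CO"), de("VOC"), dt, p)
  fine <- ch4_integrate(e, de_nox, de("CO"), de("VOC"), dt, p,
                        init_ppb = coarse$concentration$values[1L],
                        substeps = 12)
  endc <- series_value(coarse$concentration, 2019)
  endf <- series_value(fine$concentration, 2019)
  expect_lt(abs(endc - endf) / endf, 0.01)
})

test_that("paired-run differencing checks species and axes", {
  src <- constant_n2o_sources(
    c(FF = 2, soil = 9, BB = 0.7, AREC = 0.4, chem = 0.4, NREC = 0.3,
      ocean = 3.4), 1900, 1950)
  a <- n2o_integrate(src, p, init_ppbv = 280)
  expect_equal(nr_concentration_effect(a, a)$values,
               numeric(length(a$concentration$values)))
  src_off <- constant_n2o_sources(
    c(FF = 0, soil = 9, BB = 0.7, AREC = 0, chem = 0.4, NREC = 0.3,
      ocean = 3.4), 1900, 1950)
  b <- n2o_integrate(src_off, p, init_ppbv = 280)
  expect_true(all(nr_concentration_effect(a, b)$values >= 0))
  fake_ch4 <- gas_trajectory("CH4", annual_series(1900, rep(1700, 51), "ppb"))
  expect_error(nr_concentration_effect(a, fake_ch4), "species mismatch")
})
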