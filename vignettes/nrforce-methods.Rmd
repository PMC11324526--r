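---
title: "Methods: box-model attribution of the nitrogen climate effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: box-model attribution of the nitrogen climate effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrforce)
```

## The problem

Anthropogenic reactive nitrogen (Nr — all nitrogen compounds except N₂)
perturbs climate through several competing pathways.  Nitrous oxide is a
long-lived greenhouse gas and warms; ammonia and NOₓ form scattering
aerosols that cool; NOₓ raises tropospheric OH, shortening the methane
lifetime (cooling) while also producing ozone (warming); and nitrogen
inputs to land relieve N limitation, increasing the terrestrial carbon
sink and lowering CO₂ (cooling).  `nrforce` implements the
reduced-complexity chain that turns attributed nitrogen-driven fluxes into
a net direct radiative forcing with uncertainty bounds, and projects that
forcing under future emission scenarios.

The chain has four stages, each usable on its own:

1. **Factorial attribution** (`attribute_drivers()`): driver contributions
   to terrestrial fluxes (NBP, soil N₂O/NOₓ/NH₃) are differences between
   paired experiments of a factorial terrestrial-model ensemble, averaged
   across members with a 1-SD spread.
2. **Box models** (`co2_perturbation()`, `n2o_integrate()`,
   `ch4_integrate()`): zero-dimensional mass balances convert the
   attributed fluxes and emission inventories into concentration changes.
3. **Forcing aggregation** (`aggregate_net()`, `split_nonlinearity()`):
   per-agent direct forcings — diagnosed upstream by a chemical-transport /
   radiative-transfer framework and supplied here as exogenous inputs —
   are summed into the net estimate with positional bounds.
4. **Scenario projection** (`project_forcing()`): a linear projector
   carries each agent's 2019 forcing forward under per-source scaling
   factors.

## Attribution conventions

A driver's contribution is `series(expA) − series(expB)` per model, using
a declared experiment design.  The land-use-change rule is fixed to the
(SH12, SH11) pair, which isolates land-use change without confounding from
fertilizer and manure changes; all other pairs are user-declarable because
the full experiment table is not fixed by the package
(`default_experiment_design()` uses single-factor-off differencing against
the all-on run).  Direct anthropogenic Nr is the sum of the fertilizer,
manure and N-deposition contributions; irrigation, CO₂, climate and
land-use change are tracked but never counted as direct Nr effects.

Ensemble spread uses the sample standard deviation (n−1 denominator).
Within one flux, driver SDs combine in quadrature
(`anthropogenic_nr_soil_flux()`); across forcing pathways, bounds add
linearly and positionally (`aggregate_net()`), the convention that
reproduces the printed net bounds from the printed component bounds.
Bounds are stored as first/second bracket entries rather than min/max
because a warming agent carries both bounds above zero while cooling
agents list the weaker bound first.

The soil NH₃ pathway is anchored rather than taken from the ensemble
directly: the agricultural NH₃ total in 2019 is split 48% soil / 52%
livestock, the soil part follows the ensemble's temporal shape normalized
to 2019, and the livestock trajectory defaults to the same shape because
its time evolution is not independently constrained (`scale_soil_nh3()`).
Fossil-fuel emissions are the sum of all inventory sectors except
agriculture, so agricultural emissions enter only once, through the
soil/livestock pathways.

## The three box models

**CO₂.** The concentration change is the running cumulative sum of the
three direct-Nr NBP contributions times `-α/δ_CO2`, with `δ_CO2 = 2.12`
PgC ppmv⁻¹ and the airborne partitioning constant `α = 0.61`, the
atmosphere's share of the 1850–2019 carbon increase given budget increases
of 235 PgC (atmosphere) and 150 PgC (ocean); `airborne_fraction()` exposes
the full-precision ratio 235/385, and `gas_box_params()` defaults to the
two-decimal 0.61 so results match the headline convention.

**N₂O.** A one-box mass balance
`d[N2O]/dt = ΣE/δ_N2O − [N2O]/τ` with `δ_N2O = 4.8` TgN ppbv⁻¹ and a
perturbation lifetime `τ = 116` yr applied to the full concentration (as
specified, not to an anomaly).  Sources enter by category (fossil fuel,
soil, biomass burning, anthropogenic and natural river/estuary/coastal,
atmospheric chemistry, ocean).

**CH₄.** `d[CH4]/dt = −[CH4]/τ_CH4 + E/δ_CH4` with `δ_CH4 = 2.78` Tg
ppb⁻¹.  The composite lifetime combines OH oxidation harmonically with
stratospheric loss (120 yr), soil uptake (150 yr) and tropospheric
chlorine (200 yr).  The OH branch is referenced to 2005
(`τ_OH⁰ = 11.17` yr at 1783.36 ppb) and responds to the state as

```
1/τ_OH = (1/τ_OH⁰) · ( (CH4/CH4_ref)^S_OH ·
          exp(S_NOx·ΔE_NOx + S_CO·ΔE_CO + S_VOC·ΔE_VOC) + S_T·ΔT )
```

with `S_OH = −0.31`, `S_NOx = 0.0042` (Tg N yr⁻¹)⁻¹, `S_CO = −0.000105`,
`S_VOC = −0.000315`, `S_T = 0.0316` K⁻¹.  The temperature term is additive
*inside* the outer bracket, exactly as the expression is written; an
alternative multiplicative reading (`e^{S_T·ΔT}`) would be defensible, but
the package implements the expression literally and near the reference
state the two differ only at second order.  Emission departures ΔE are
global totals (anthropogenic plus biomass burning) minus their 2005
values.

### Numerical choices

The integrator is explicit Euler with Δt = 1 yr — the scheme implied by
annual source data — with the concentration stored at the start of each
year.  A `substeps` argument refines the step (12 ≈ monthly) and serves as
a cross-check, never the default.  The discrete annual fixed point of the
N₂O box equals the analytic steady state `τE/δ` exactly, so steady-state
behaviour is scheme-independent; during transients the annual truncation
error peaks near one lifetime at about 0.16% of the initial value for a
pure decay and is far smaller for realistic ramped sources (the test suite
pins annual-vs-monthly agreement at 1% at the 2019 endpoint and an
independent `deSolve` integration to 0.5%).  Initial concentrations
default to the steady state implied by first-year sources, since
pre-industrial initial values are otherwise unconstrained; paired
with/without runs share one initial state so their difference is purely
source-driven.

## Forcing aggregation and the source split

The per-agent 2019 forcings relative to 1850 are exogenous diagnosed
values (`historical_forcing_2019()`): CO₂ −0.12 (−0.07, −0.17), N₂O +0.16
(+0.14, +0.17), CH₄ −0.19 (−0.12, −0.29), aerosols −0.24 (−0.18, −0.28)
and O₃ +0.05 (+0.03, +0.07) W m⁻², with aerosols carried as one aggregate
agent (ammonium + nitrate + sulfate).  Their sum is the net −0.34 (−0.20,
−0.50) W m⁻².  When the forcing is split into agricultural (soil fluxes
from fertilizer and manure) and non-agricultural (fossil fuel plus
N-deposition-driven soil fluxes) sources, nonlinear aerosol chemistry
makes the two split nets (−0.19 each) sum to −0.38 W m⁻², over-cooling the
combined estimate by the residual −0.04 W m⁻² that
`split_nonlinearity()` reports.  The CH₄–N₂O spectral-overlap unmasking
term (+0.11 → +0.07 W m⁻² for non-agricultural N₂O, i.e. 0.04 W m⁻²) is
bookkept by `unmasking_adjustment()`; the overlap computation itself is
out of scope.

The radiative sensitivities S_CO2/S_N2O/S_CH4 that map concentration
changes to forcing were diagnosed upstream and are not public; the
`sensitivity_constants()` defaults (0.013 W m⁻² ppmv⁻¹, 0.003 W m⁻²
ppbv⁻¹, 0.00036 W m⁻² ppb⁻¹) are clearly-labelled illustrative magnitudes
from standard simplified expressions.  Every headline number above
bypasses them by construction.

## Scenario projection

`project_forcing()` advances each agent from its 2019 value under
per-source scaling factors anchored at 1.0 in 2019:

* CO₂ accumulates annual increments of the scaled present-day
  (2015–2019 mean) NBP driver contributions times `α/δ_CO2 · S_CO2`, with
  land uptake cooling.  The projector treats the scaled present-day
  contribution as an annual increment rather than rescaling a 5-year
  block, which keeps the 2019 handoff continuous.
* N₂O and CH₄ continue their box models from the 2019 concentrations.
  Fossil N₂O follows its own factor (tied to fossil NOₓ in the shipped
  archetypes, since fossil N₂O projections track fossil NOₓ development);
  soil anthropogenic N₂O scales per driver, which makes the N₂O forcing
  monotone in the fertilizer factor.  Soil-gas responses are linear in the
  scaling factors, reflecting the assumption that Nr-driven fluxes scale
  with Nr addition.
* Aerosol forcing scales with the (NOₓ + NH₃) emission ratio to 2019 and
  O₃ with the NOₓ ratio — both exactly homogeneous of degree 1.  Livestock
  NH₃ follows the manure factor, as a manure-management emission; the
  scenario vocabulary has no separate livestock source.
* Bounds inherit the historical percentage ranges multiplicatively, and
  net bounds add positionally across agents, matching the historical
  convention.

The three shipped archetypes (`generate_scenarios()`) are illustrative
shapes only — a "cleaner" pathway (fossil NOₓ falling to 0.2 by 2050), a
"fertilizer-growth" pathway (fertilizer/manure rising to 1.5/1.4) and a
"flat" pathway.  The actual pathway-family scaling factors are not
reproduced here, so the projector's published deltas are property targets
(identities, homogeneity, monotonicity, continuity) rather than numerical
reproductions.

## The synthetic fixture

`generate_inventory()` and `generate_ensemble()` emulate the *statistical
structure* the analysis assumes, not real datasets.  Anthropogenic growth
is logistic in time and anchored to zero at 1850, so pre-industrial
anthropogenic emissions vanish by construction.  The fixture is calibrated
to the present-day (2016–2019 mean on the default 1850–2019 axis) targets:
0.55 ± 0.38 PgC yr⁻¹ direct-Nr NBP; soil N₂O of 2.7 ± 0.95 (fertilizer +
manure), 0.80 ± 0.22 (N deposition) and 6.2 ± 1.6 (natural) TgN yr⁻¹;
46.5 TgN yr⁻¹ total anthropogenic NOₓ of which 3.1 ± 0.77 is soil; and
2019 NH₃ totals of 50.5 (all sources) and 38.2 (agricultural) TgN yr⁻¹.
The 46.5 target is met by the fossil (non-agricultural inventory) and
attributed-soil components jointly — calibrating the inventory alone to
46.5 would double-book the soil flux.

Inter-model spread is multiplicative log-normal, affinely standardized so
the finite-member sample mean and SD hit their targets exactly; within a
calibrated driver group the per-member multipliers are made mutually
sample-orthogonal with per-driver SDs proportional to the driver means, so
the quadrature combination of driver SDs and the member-level SD of the
summed contribution coincide at the group target.  (The three-member soil
NOₓ ensemble cannot support three orthogonal spread directions, so its
drivers share one multiplier and only the member-level SD is calibrated.)
Multipliers are constant in time; model-internal interannual noise lives
in the natural baseline and is identical across one model's experiments,
which is what makes factorial differencing recover the injected effects
bit-exactly.  Member availability mirrors the source ensemble: 8 members
for NBP and soil N₂O, 6 for soil NH₃, 3 for soil NOₓ.

What the fixture does *not* emulate: spatial structure, correlated
interannual variability between models, trends in natural baselines,
non-additive driver interactions, and the actual inventory/ensemble
numerical values beyond the named targets.  Passing tests therefore
demonstrate that the *machinery* is correct under the stated statistical
assumptions, not that real-data attribution would yield these numbers.
N₂O source categories whose magnitudes are not public (biomass burning
0.7, anthropogenic river/estuary/coastal 0.4, chemistry 0.4, natural
river/estuary/coastal 0.3, ocean 3.4, fossil fuel ≈ 2.0 TgN yr⁻¹ in 2019)
use standard global-budget magnitudes and are synthetic placeholders.

## Worked example

```{r example}
fc <- fixture_config(seed = 1)
inv <- generate_inventory(fc)
at <- attribute_drivers(generate_ensemble(fc))

nbp <- anthropogenic_nr_soil_flux(at, "NBP")
c(mean = series_mean(nbp$mean, 2016, 2019),
  sd = series_mean(nbp$sd, 2016, 2019))

aggregate_net(historical_forcing_2019())

proj <- project_forcing(generate_scenarios(fc)$cleaner, horizon_year = 2050)
subset(as.data.frame(proj), year == 2050 & agent == "net")
```

## Problem sizes and limitations

All computations run on annual global scalars (170-year histories, eight
ensemble members, ten experiments, four flux kinds), so the full pipeline
completes in well under a second and the test suite in a few seconds.

Known limitations: forcings for aerosols and O₃ cannot be computed from
first principles here (they require a chemical-transport and
radiative-transfer model) and enter as exogenous constants; the radiative
sensitivities are placeholders; gridded fields, monthly resolution, ocean
N fertilization, aerosol–cloud interactions and soil CH₄ uptake are out of
scope; and the projector is linear by design, with the optional
N-saturation ceiling (`nbp_saturation`) off by default so the headline
behaviour stays the stated linear assumption.
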