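Package: nrforce
Title: Net Radiative Forcing of Anthropogenic Reactive Nitrogen with
    Reduced-Complexity Box Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the net direct radiative forcing of anthropogenic
    reactive nitrogen (Nr) with a chain of reduced-complexity models:
    factorial attribution of nitrogen-driven terrestrial fluxes from a
    multi-model ensemble, one-box atmospheric mass balances for CO2, N2O
    and CH4 (including the OH-driven methane lifetime feedback),
    aggregation of per-agent forcings into a net estimate with
    uncertainty bounds and an agricultural/non-agricultural source
    split, and a linear projector of forcing under future emission
    scenarios.  A calibrated synthetic-data module emulates the sectoral
    emission inventory and the factorial terrestrial-model ensemble so
    the full pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
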