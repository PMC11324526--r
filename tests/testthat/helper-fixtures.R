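# Shared builders for small hand-constructed fixtures.

const_series <- function(value, units = "TgN yr-1", start = 2000L, n = 5L) {
  annual_series(start, rep(value, n), units)
}

# A miniature additive factorial set: per model, experiment values are a
# natural baseline plus the injected effects of the drivers switched on.
# `effects` is a named list model_id -> named numeric of driver effects.
tiny_runs <- function(effects, natural = 5, flux_kind = "soilN2O",
                      units = "TgN yr-1", start = 2000L, n = 5L) {
  drivers <- names(effects[[1L]])
  off_table <- c(list(SH1 = character(0)),
                 stats::setNames(lapply(drivers, identity),
                                 paste0("OFF_", drivers)),
                 list(SH9 = drivers))
  runs <- list()
  for (m in names(effects)) {
    for (ex in names(off_table)) {
      on <- setdiff(drivers, off_table[[ex]])
      v <- natural + sum(unlist(effects[[m]])[on])
      runs[[paste(m, ex)]] <- factorial_run(
        m, ex, flux_kind, const_series(v, units, start, n))
    }
  }
  unname(runs)
}

tiny_design <- function(drivers = c("fertilizer", "manure", "Ndep")) {
  experiment_design(
    stats::setNames(lapply(drivers, function(d) c("SH1", paste0("OFF_", d))),
                    drivers),
    natural_experiment = "SH9")
}

# Paper-anchored component set used across forcing tests.
paper_components <- function() historical_forcing_2019()
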