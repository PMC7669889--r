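# Shared fixtures and helpers, built in code once per test run.

coreNet <- buildCoreModel()
coreNetRubp <- buildCoreModel(includeRubp = TRUE)
prepNet <- addCurrencyExchanges(pruneForSearch(coreNet))
prepNetRubp <- addCurrencyExchanges(pruneForSearch(coreNetRubp))

# canonical sorted key of a pathway's directed support
supportKey <- function(p) {
  s <- pathwaySupport(p)
  paste(sort(paste0(s$id, ":", s$direction)), collapse = ";")
}

# A 5-reaction toy with exactly one route achieving 3 CO2 -> 1 pyruvate:
# R1 (co2 + a -> b) three times plus R2 (3 b -> pyr + 3 a).  R3-R5 are
# carbon-balanced decoys feeding dead-end species, so steady state forces
# them to zero flux.
toySingleRoute <- function() {
  mets <- data.frame(
    id = c("co2_c", "a_c", "b_c", "pyr_c", "d_c", "f_c", "g_c"),
    carbons = c(1L, 2L, 3L, 3L, 4L, 4L, 7L),
    compartment = "c",
    is_currency = c(TRUE, rep(FALSE, 6)))
  sto <- list(
    R1 = c(co2_c = -1, a_c = -1, b_c = 1),
    R2 = c(b_c = -3, pyr_c = 1, a_c = 3),
    R3 = c(pyr_c = -1, co2_c = -1, d_c = 1),
    R4 = c(a_c = -2, f_c = 1),
    R5 = c(b_c = -1, d_c = -1, g_c = 1))
  rxns <- data.frame(id = names(sto),
                     dg0_prime = c(-5, -10, -20, 0, -10))
  MetabolicNetwork(mets, rxns, sto, provenance = "toy single route")
}

# toy where pyruvate is unreachable from CO2
toyNoRoute <- function() {
  mets <- data.frame(id = c("co2_c", "a_c", "b_c", "pyr_c"),
                     carbons = c(1L, 2L, 3L, 3L), compartment = "c",
                     is_currency = c(TRUE, FALSE, FALSE, FALSE))
  sto <- list(R1 = c(co2_c = -1, a_c = -1, b_c = 1),
              R2 = c(b_c = -1, a_c = 1, co2_c = 1))
  MetabolicNetwork(mets, data.frame(id = names(sto), dg0_prime = c(-5, -5)),
                   sto, provenance = "toy no route")
}

writeMinimalBigg <- function(path) {
  model <- list(
    id = "mini",
    metabolites = list(
      list(id = "a_c", name = "A", formula = "C3H6O3", compartment = "c"),
      list(id = "b_c", name = "B", formula = "C3H6O3", compartment = "c"),
      list(id = "b_e", name = "B", formula = "C3H6O3", compartment = "e")),
    reactions = list(
      list(id = "R1", metabolites = list(a_c = -1, b_c = 1),
           lower_bound = -1000, upper_bound = 1000),
      list(id = "Bt", metabolites = list(b_c = -1, b_e = 1),
           lower_bound = -1000, upper_bound = 1000)))
  jsonlite::write_json(model, path, auto_unbox = TRUE, digits = NA)
  path
}
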