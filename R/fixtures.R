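## Synthetic-data generation: the curated core-metabolism fixture, random
## carbon-balanced networks for oracle tests, and noisy kinetic assay data.

## run expr with a private RNG stream seeded by `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build the bundled central-metabolism fixture network
#'
#' Returns a ~45-reaction core model (glycolysis/gluconeogenesis with PEP
#' synthetase, Entner-Doudoroff pathway, oxidative and non-oxidative pentose
#' phosphate pathway, xylose uptake, fermentation sinks, adenylate/redox
#' bookkeeping) in which every internal reaction carries a vendored dG'0 and
#' every metabolite a full-molecule carbon count.  Dissolved CO2 is fixed at
#' the Henry-law concentration of 200 mbar; O2 at 1 mM.
#'
#' @param includeRubp add phosphoribulokinase (PRK) and Rubisco (RBPC).
#' @param includeTca add a compact TCA/anaplerosis block (PPC, CS ...
#'   SUCOAS, MDH, FUM) with a succinate sink.
#' @param co2Mbar CO2 partial pressure (mbar) that pins the dissolved CO2
#'   concentration.
#' @param params a [ThermoParams-class] (Henry constant).
#' @return a [MetabolicNetwork-class].
#' @export
#' @examples
#' net <- buildCoreModel()
#' carbonBalanceCheck(net)   # character(0): authored carbon-balanced
buildCoreModel <- function(includeRubp = FALSE, includeTca = FALSE,
                           co2Mbar = 200, params = thermoParams()) {
  groups <- c("core", "transport", "exchange",
              if (includeRubp) "rubp",
              if (includeTca) c("tca", "tca_transport", "tca_exchange"))
  defs <- Filter(function(d) d[[7]] %in% groups, .FIXTURE_REACTIONS)
  sto <- list(); rows <- list()
  for (d in defs) {
    parsed <- .parseEquation(d[[2]])
    sto[[d[[1]]]] <- parsed$stoich
    rows[[d[[1]]]] <- data.frame(
      id = d[[1]], dg0_prime = d[[3]], lower_bound = d[[4]],
      upper_bound = d[[5]], oxygen_sensitive = d[[6]],
      is_exchange = grepl("^EX_", d[[1]]),
      is_transport = d[[7]] %in% c("transport", "tca_transport"),
      is_pseudo = FALSE,
      notes = if (is.na(d[[3]])) "" else .DG0_PROVENANCE,
      stringsAsFactors = FALSE)
  }
  rxns <- do.call(rbind, rows)
  ## o2 takes part in no fixture reaction but belongs to the currency set
  ## (free supply; fixed at 1 mM for thermodynamics)
  metIds <- sort(unique(c(unlist(lapply(sto, names)), "o2_c")))
  base <- .baseId(metIds)
  mets <- data.frame(
    id = metIds,
    name = unname(.FIXTURE_NAMES[base]),
    carbons = unname(.FIXTURE_CARBONS[base]),
    compartment = .compartmentOf(metIds),
    is_currency = base %in% currencyBaseIds(),
    fixed_conc = NA_real_, stringsAsFactors = FALSE)
  mets$fixed_conc[mets$id == "co2_c"] <- co2PressureToConc(co2Mbar, params)
  mets$fixed_conc[mets$id == "o2_c"] <- 1e-3
  MetabolicNetwork(mets, rxns, sto,
                   provenance = sprintf(
                     "latentpath core fixture (rubp=%s, tca=%s)",
                     includeRubp, includeTca))
}

#' Random carbon-balanced network for oracle tests
#'
#' Generates a small network over metabolites that include the search
#' substrate (`co2_c`, 1 carbon) and product (`pyr_c`, 3 carbons), with
#' random sparse integer stoichiometries (coefficients in -2..2) that are
#' carbon-balanced by construction, random dG'0 in [-40, 40] kJ/mol, and a
#' connected substrate-usage graph.  Currency metabolites are avoided so
#' the brute-force oracle stays simple.
#'
#' @param nMetabolites,nReactions network size (`nReactions` <= 12 for
#'   oracle use).
#' @param seed integer seed; identical seeds give identical networks.
#' @param maxTries attempts before giving up.
#' @return a [MetabolicNetwork-class].
#' @export
randomNetwork <- function(nMetabolites = 8, nReactions = 8, seed = 1,
                          maxTries = 1000) {
  stopifnot(nMetabolites >= 4, nReactions >= 2)
  .withSeed(seed, {
    for (try in seq_len(maxTries)) {
      net <- .randomNetworkOnce(nMetabolites, nReactions)
      if (!is.null(net)) return(net)
    }
    stop("could not construct a connected carbon-balanced network in ",
         maxTries, " attempts", call. = FALSE)
  })
}

.randomNetworkOnce <- function(nMetabolites, nReactions) {
  ids <- c("co2_c", "pyr_c",
           paste0("m", seq_len(nMetabolites - 2), "_c"))
  carbons <- c(1L, 3L, sample(1:4, nMetabolites - 2, replace = TRUE))
  ## one random balanced sparse row; NULL when the draw fails
  drawReaction <- function(mustUse = integer()) {
    for (k in 1:200) {
      nPart <- sample(3:4, 1)
      part <- unique(c(mustUse, sample(nMetabolites, nPart)))[seq_len(nPart)]
      coef <- sample(c(-2, -1, 1, 2), length(part), replace = TRUE)
      bal <- sum(coef * carbons[part])
      if (bal == 0 && any(coef > 0) && any(coef < 0)) {
        return(stats::setNames(coef, ids[part]))
      }
    }
    NULL
  }
  sto <- list()
  for (j in seq_len(nReactions)) {
    mustUse <- if (j == 1) 1L else if (j == 2) 2L else integer()
    rx <- drawReaction(mustUse)
    if (is.null(rx)) return(NULL)
    sto[[paste0("R", j)]] <- rx
  }
  ## connectivity of the metabolite-reaction bipartite graph
  used <- unique(unlist(lapply(sto, names)))
  adj <- lapply(sto, names)
  comp <- adj[[1]]
  repeat {
    grow <- unique(unlist(adj[vapply(adj, function(a)
      any(a %in% comp), logical(1))]))
    if (length(grow) == length(comp)) break
    comp <- grow
  }
  if (!setequal(comp, used)) return(NULL)
  if (!all(c("co2_c", "pyr_c") %in% used)) return(NULL)
  base <- .baseId(used)
  mets <- data.frame(id = used, name = used,
                     carbons = carbons[match(used, ids)],
                     compartment = "c", is_currency = FALSE,
                     fixed_conc = NA_real_, stringsAsFactors = FALSE)
  mets$is_currency[mets$id == "co2_c"] <- TRUE
  rxns <- data.frame(id = names(sto),
                     dg0_prime = round(stats::runif(length(sto), -40, 40), 2),
                     lower_bound = -1000, upper_bound = 1000,
                     oxygen_sensitive = FALSE, is_exchange = FALSE,
                     is_transport = FALSE, is_pseudo = FALSE, notes = "",
                     stringsAsFactors = FALSE)
  MetabolicNetwork(mets, rxns, sto, provenance = "random oracle network")
}

#' Synthetic Michaelis-Menten assay data
#'
#' Emulates an initial-rate assay design: `n` substrate concentrations
#' log-spaced over `[km/10, 10 km]` with multiplicative Gaussian noise on
#' the rates.
#'
#' @param params a [kineticParams()] ground truth.
#' @param n number of points (>= 4).
#' @param noise_cv coefficient of variation of the rate noise.
#' @param seed integer seed.
#' @return data.frame with columns `substrate_mM`, `rate`.
#' @export
synthMmData <- function(params, n = 15, noise_cv = 0.05, seed = 1) {
  stopifnot(n >= 4)
  s <- 10^seq(log10(params$km / 10), log10(10 * params$km), length.out = n)
  v <- mmRate(s, params)
  .withSeed(seed, {
    data.frame(substrate_mM = s,
               rate = v * (1 + stats::rnorm(n, 0, noise_cv)))
  })
}

#' Write all fixture files to a directory
#'
#' Emits `metabolites.tsv`/`reactions.tsv` (the core model),
#' `dg0_prime.tsv` (vendored reaction Gibbs energies with provenance),
#' `atom_maps.tsv` (the positional carbon maps used by the labeling
#' simulator) and `assay_synth.tsv` (synthetic kinetic assay data).
#'
#' @param dir output directory.
#' @param includeRubp,includeTca forwarded to [buildCoreModel()].
#' @param seed seed for the synthetic assay data.
#' @return `dir`, invisibly.
#' @export
writeFixtures <- function(dir, includeRubp = FALSE, includeTca = FALSE,
                          seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- buildCoreModel(includeRubp = includeRubp, includeTca = includeTca)
  writeNetworkTable(net, dir)
  r <- reactions(net)
  keep <- !is.na(r$dg0_prime)
  dg <- data.frame(id = r$id[keep], dg0_prime_kj_mol = r$dg0_prime[keep],
                   provenance = .DG0_PROVENANCE)
  utils::write.table(dg, file.path(dir, "dg0_prime.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(atomMapTable(), file.path(dir, "atom_maps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  assay <- synthMmData(kineticParams(kcat = 4.7, km = 0.9), n = 15,
                       noise_cv = 0.05, seed = seed)
  utils::write.table(assay, file.path(dir, "assay_synth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
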