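## End-to-end orchestration: configuration handling and the full analysis
## (preprocess -> search -> MDF/Pareto -> FBA -> labeling) with a
## deterministic output directory layout.

.RUN_CONFIG_TYPES <- list(
  model = "character", include_rubp = "logical", include_tca = "logical",
  seed = "numeric", max_solutions = "numeric", weight = "numeric",
  exclude_oxygen_sensitive = "logical", co2_mbar = "numeric",
  conc_lb = "numeric", conc_ub = "numeric",
  substrate = "character", uptake = "numeric", atpm = "numeric",
  aerobic = "logical", h2_donor = "logical", products = "character",
  variants = "character", tracer_substrate = "character",
  tracer_positions = "numeric", tracer_co2 = "logical")

#' Default run configuration
#'
#' @return named list of all run options with their defaults: the fixture
#'   model, the 3 CO2 -> 1 pyruvate query at 200 mbar CO2, concentration
#'   bounds 1 uM - 10 mM, xylose FBA at 10.8 mmol/gDW/h with ATPM 6.86, and
#'   the 1-13C-xylose + 13CO2 tracer.
#' @export
defaultRunConfig <- function() {
  list(model = "fixture", include_rubp = FALSE, include_tca = FALSE,
       seed = 1, max_solutions = 6, weight = 1,
       exclude_oxygen_sensitive = FALSE, co2_mbar = 200,
       conc_lb = 1e-6, conc_ub = 1e-2,
       substrate = "EX_xyl__D_e", uptake = 10.8, atpm = 6.86,
       aerobic = FALSE, h2_donor = FALSE,
       products = c("EX_ac_e", "EX_lac__D_e", "EX_etoh_e"),
       variants = c("GED_shunt", "RuBP_shunt"),
       tracer_substrate = "xylose", tracer_positions = 1,
       tracer_co2 = TRUE)
}

#' Validate a run configuration
#'
#' Accepts a list or a path to a YAML/JSON file; rejects unknown keys,
#' type-checks every field, checks value constraints (positive uptake,
#' 0 < conc_lb <= conc_ub, ...) and fills defaults, reporting every default
#' substituted via `message()`.  All problems are aggregated into one
#' error.
#'
#' @param config list or file path.
#' @return the completed configuration list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) {
    path <- config
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    config <- if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package",
             call. = FALSE)
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- defaultRunConfig()
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste("unknown config key(s):",
                          paste(unknown, collapse = ", ")))
  out <- defaults
  for (key in intersect(names(config), names(defaults))) {
    val <- config[[key]]
    type <- .RUN_CONFIG_TYPES[[key]]
    ok <- switch(type,
                 numeric = is.numeric(val),
                 logical = is.logical(val) && !anyNA(val),
                 character = is.character(val))
    if (!ok) {
      errs <- c(errs, sprintf("field '%s' must be %s, got %s",
                              key, type, class(val)[1]))
    } else {
      out[[key]] <- val
    }
  }
  if (!length(errs)) {
    if (out$uptake <= 0) errs <- c(errs, "field 'uptake' must be > 0")
    if (out$atpm < 0) errs <- c(errs, "field 'atpm' must be >= 0")
    if (out$co2_mbar < 0) errs <- c(errs, "field 'co2_mbar' must be >= 0")
    if (!(out$conc_lb > 0 && out$conc_lb <= out$conc_ub))
      errs <- c(errs, "need 0 < conc_lb <= conc_ub")
    if (out$weight < 0) errs <- c(errs, "field 'weight' must be >= 0")
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  defaulted <- setdiff(names(defaults), names(config))
  if (length(defaulted))
    message("config defaults used for: ", paste(defaulted, collapse = ", "))
  out
}

.loadModel <- function(config) {
  if (identical(config$model, "fixture")) {
    buildCoreModel(includeRubp = config$include_rubp,
                   includeTca = config$include_tca,
                   co2Mbar = config$co2_mbar)
  } else if (grepl("\\.json$", config$model)) {
    readBiggJson(config$model)
  } else {
    readNetworkTable(config$model)
  }
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: model loading, preprocessing (pruning + currency
#' pseudo-reactions), MILP pathway enumeration, MDF evaluation and Pareto
#' ranking, FBA variant yield comparison, and labeling prediction; writes a
#' deterministic file layout (`config.json`, `pathways.json`, `pareto.tsv`,
#' `mdf.tsv`, `yields.tsv`, `labeling.tsv`, `report.md`) into `outdir`.
#'
#' @param config a configuration list or file path (see
#'   [validateConfig()]).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`pathways`,
#'   `pareto`, `yields`, `labeling`).
#' @export
runFullAnalysis <- function(config = defaultRunConfig(), outdir) {
  config <- validateConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config[order(names(config))],
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  set.seed(config$seed)
  bounds <- concentrationBounds(config$conc_lb, config$conc_ub)
  net <- .loadModel(config)

  ## search + thermodynamic ranking
  pws <- enumeratePathways(net, bounds = bounds,
                           maxSolutions = config$max_solutions,
                           w = config$weight,
                           excludeOxygenSensitive =
                             config$exclude_oxygen_sensitive)
  pwRecords <- lapply(seq_along(pws), function(i) {
    p <- pws[[i]]
    list(rank = i,
         support = p@support$id,
         directions = p@support$direction,
         fluxes = as.list(round(p@fluxes, 10)),
         mdf_kj_mol = p@mdf,
         n_reactions = p@nReactions,
         net_conversion = as.list(round(p@netConversion, 10)))
  })
  jsonlite::write_json(pwRecords, file.path(outdir, "pathways.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pwTab <- data.frame(
    rank = seq_along(pws),
    n_reactions = vapply(pws, function(p) p@nReactions, integer(1)),
    mdf_kj_mol = round(vapply(pws, function(p) p@mdf, numeric(1)), 6))
  front <- paretoFront(pws)
  frontKeys <- vapply(front, .arcKey, character(1))
  pwTab$pareto_optimal <- vapply(pws, .arcKey, character(1)) %in% frontKeys
  .writeTsv(pwTab, file.path(outdir, "pareto.tsv"))
  prep <- .prepareForSearch(net)
  mdfRows <- list()
  for (i in seq_along(pws)) {
    res <- computeMdf(prep, pws[[i]], bounds)
    mdfRows[[i]] <- data.frame(rank = i, reaction = names(res@reactionDgPrime),
                               dg_prime_kj_mol = round(res@reactionDgPrime, 6),
                               bottleneck = names(res@reactionDgPrime) %in%
                                 res@bottlenecks)
  }
  if (length(mdfRows))
    .writeTsv(do.call(rbind, mdfRows), file.path(outdir, "mdf.tsv"))
  else .writeTsv(data.frame(rank = integer(), reaction = character(),
                            dg_prime_kj_mol = numeric(),
                            bottleneck = logical()),
                 file.path(outdir, "mdf.tsv"))

  ## FBA yields
  curated <- suppressWarnings(applyCurations(net))
  yields <- suppressWarnings(
    relativeYieldTable(curated, config$variants, config$products,
                               fbaConfig(substrate = config$substrate,
                                         uptake = config$uptake,
                                         atpm = config$atpm,
                                         aerobic = config$aerobic,
                                         h2_donor = config$h2_donor)))
  yields$yield <- round(yields$yield, 6)
  yields$relative_yield <- round(yields$relative_yield, 6)
  .writeTsv(yields, file.path(outdir, "yields.tsv"))

  ## labeling predictions
  tracer <- tracerSpec(config$tracer_substrate, config$tracer_positions,
                       config$tracer_co2)
  iso <- aminoAcidIsotopologues(tracer)
  maxLen <- max(lengths(iso))
  labTab <- do.call(rbind, lapply(names(iso), function(sp) {
    f <- c(iso[[sp]], numeric(maxLen - length(iso[[sp]])))
    stats::setNames(data.frame(sp, t(f)), c("species", .mplus(maxLen - 1)))
  }))
  .writeTsv(labTab, file.path(outdir, "labeling.tsv"))

  ## report
  lines <- c("# Latent carbon-fixation analysis report", "")
  if (length(pws)) {
    top <- pws[[1L]]
    gedPrep <- prep
    lines <- c(lines,
      sprintf("Top-ranked pathway: %d reactions, MDF %.2f kJ/mol, ATP cost %.2f per mole product.",
              top@nReactions, top@mdf, atpCost(top, gedPrep)),
      sprintf("Support: %s.",
              paste0(top@support$id,
                     ifelse(top@support$direction < 0, " (reverse)", ""),
                     collapse = ", ")),
      sprintf("Net conversion: %s.",
              paste(sprintf("%s %+g", names(top@netConversion),
                            round(top@netConversion, 6)), collapse = ", ")),
      sprintf("Pareto front: %d of %d enumerated pathway(s).",
              length(front), length(pws)))
  } else {
    lines <- c(lines, "No feasible pathway found for the query.")
  }
  lines <- c(lines, "",
             "## Variant yield comparison (mol product / mol substrate)", "")
  for (p in unique(yields$product)) {
    sub <- yields[yields$product == p, ]
    lines <- c(lines, sprintf("- %s: %s", p,
      paste(sprintf("%s %.3f", sub$variant, sub$yield), collapse = ", ")))
  }
  writeLines(lines, file.path(outdir, "report.md"))
  invisible(list(pathways = pws, pareto = front, yields = yields,
                 labeling = iso))
}
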