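## Flux balance analysis of non-growing cells: model curations, pathway
## variants (GED / RuBP cycles and shunts), and maximal product yields.

#' FBA configuration
#'
#' @param substrate exchange id or extracellular metabolite id of the carbon
#'   source (default xylose).
#' @param uptake fixed uptake rate, mmol/gDW/h (xylose 10.8, glucose 13.1:
#'   measured rates for anaerobic fermentative growth).
#' @param atpm non-growth-associated ATP maintenance flux, mmol/gDW/h
#'   (default 6.86), held fixed.
#' @param aerobic logical; aerobic conditions deactivate the
#'   oxygen-sensitive formate lyases and open O2 uptake.
#' @param h2_donor logical; add an irreversible hydrogen dehydrogenase
#'   (H2DH) and unconstrained H2 uptake as an auxiliary electron donor.
#' @param product exchange id or metabolite id of the product to maximize.
#' @return a validated list.
#' @export
fbaConfig <- function(substrate = "EX_xyl__D_e", uptake = 10.8,
                      atpm = 6.86, aerobic = FALSE, h2_donor = FALSE,
                      product = "EX_ac_e") {
  stopifnot(uptake > 0, atpm >= 0)
  list(substrate = substrate, uptake = uptake, atpm = atpm,
       aerobic = aerobic, h2_donor = h2_donor, product = product)
}

## id synonyms between genome-scale models and the fixture
.RXN_SYNONYMS <- c(G6PDH2r = "ZWF")

.resolveRxnId <- function(net, id) {
  ids <- reactionIds(net)
  if (id %in% ids) return(id)
  alt <- if (id %in% names(.RXN_SYNONYMS)) .RXN_SYNONYMS[[id]] else NULL
  if (!is.null(alt) && alt %in% ids) return(alt)
  NA_character_
}

.setBounds <- function(net, id, lb, ub) {
  r <- reactions(net)
  r$lower_bound[r$id == id] <- lb
  r$upper_bound[r$id == id] <- ub
  methods::initialize(net, reactions = r)
}

.removeReactions <- function(net, ids) {
  .subsetReactions(net, !(reactions(net)$id %in% ids))
}

.addReaction <- function(net, id, stoich, dg0 = NA_real_, lb = -1000,
                         ub = 1000, notes = "") {
  if (id %in% reactionIds(net))
    stop("reaction id already exists: ", id, call. = FALSE)
  sto <- .stoichAsList(net)
  sto[[id]] <- stoich
  newMets <- setdiff(names(stoich), metaboliteIds(net))
  m <- metabolites(net)
  if (length(newMets)) {
    base <- .baseId(newMets)
    m <- rbind(m, data.frame(id = newMets,
                             name = ifelse(base %in% names(.FIXTURE_NAMES),
                                           .FIXTURE_NAMES[base], newMets),
                             carbons = ifelse(base %in% names(.FIXTURE_CARBONS),
                                              .FIXTURE_CARBONS[base],
                                              NA_integer_),
                             compartment = .compartmentOf(newMets),
                             is_currency = base %in% currencyBaseIds(),
                             fixed_conc = NA_real_))
  }
  rxns <- rbind(reactions(net),
                data.frame(id = id, dg0_prime = dg0, lower_bound = lb,
                           upper_bound = ub, oxygen_sensitive = FALSE,
                           is_exchange = grepl("^EX_", id),
                           is_transport = FALSE, is_pseudo = FALSE,
                           notes = notes))
  MetabolicNetwork(m, rxns, sto[rxns$id], provenance = net@provenance)
}

#' Apply the standard model curations for yield prediction
#'
#' Applies eight curation classes to a genome-scale model (each skipped
#' with a warning when its reaction ids are absent, so toy models pass
#' through unchanged): (i) transhydrogenase THD2pp translocates one proton
#' instead of two; (ii) homoserine dehydrogenase HSDy made irreversible
#' toward homoserine; (iii) GLYCK and POR5 removed; (iv) exchanges of Fe2+,
#' H2S, methionine and cysteine removed; (v) threonine cleavage (THRA,
#' THRD, GLYAT) blocked; (vi) DRPA and PAI2T removed; (vii) GLCDpp removed;
#' (viii) the formate lyases PFL and OBTFL flagged oxygen-sensitive (they
#' are deactivated only under aerobic conditions, at solve time).
#'
#' @param net a [MetabolicNetwork-class].
#' @return the curated network (idempotent).
#' @export
applyCurations <- function(net) {
  warn <- function(cls, ids) warning("curation ", cls, ": id(s) not in model (",
                                     paste(ids, collapse = ", "), "), skipped",
                                     call. = FALSE)
  ## (i) THD2pp proton stoichiometry
  if ("THD2pp" %in% reactionIds(net)) {
    sto <- .stoichAsList(net)
    v <- sto$THD2pp
    hIds <- names(v)[.baseId(names(v)) == "h"]
    if (length(hIds) && any(abs(v[hIds]) > 1)) {
      v[hIds] <- v[hIds] / 2
      sto$THD2pp <- v
      net <- MetabolicNetwork(metabolites(net), reactions(net),
                              sto[reactionIds(net)],
                              provenance = net@provenance)
    }
  } else warn("i (THD2pp)", "THD2pp")
  ## (ii) HSDy irreversible toward homoserine (reverse of written direction)
  if ("HSDy" %in% reactionIds(net)) {
    net <- .setBounds(net, "HSDy", -1000, 0)
  } else warn("ii (HSDy)", "HSDy")
  ## (iii) disputable reactions removed
  for (spec in list(c("iii", "GLYCK", "POR5"),
                    c("iv", "EX_fe2_e", "EX_h2s_e", "EX_met__L_e",
                      "EX_cys__L_e"),
                    c("vi", "DRPA", "PAI2T"),
                    c("vii", "GLCDpp"))) {
    cls <- spec[1]; ids <- spec[-1]
    present <- intersect(ids, reactionIds(net))
    if (length(present)) net <- .removeReactions(net, present)
    else warn(cls, ids)
  }
  ## (v) threonine cleavage blocked
  thr <- intersect(c("THRA", "THRD", "GLYAT"), reactionIds(net))
  if (length(thr)) {
    for (id in thr) net <- .setBounds(net, id, 0, 0)
  } else warn("v (threonine cleavage)", c("THRA", "THRD", "GLYAT"))
  ## (viii) oxygen-sensitive formate lyases: flag; blocked when aerobic
  fl <- intersect(c("PFL", "OBTFL"), reactionIds(net))
  if (length(fl)) {
    r <- reactions(net)
    r$oxygen_sensitive[r$id %in% fl] <- TRUE
    net <- methods::initialize(net, reactions = r)
  } else warn("viii (formate lyases)", c("PFL", "OBTFL"))
  net
}

.SHUNT_BLOCKS <- c("PFK", "PFK_3", "F6PA", "G6PDH2r", "FBP")

#' Specification of a pathway variant
#'
#' The five variants compared in the yield analysis: `WT` (canonical sugar
#' utilization), `GED_shunt`/`RuBP_shunt` (linear carboxylation routes,
#' upper-glycolysis re-entry blocked) and `GED_cycle`/`RuBP_cycle`.  Shunt
#' variants block phosphofructokinase (PFK and PFK_3), fructose 6-phosphate
#' aldolase (F6PA), glucose 6-phosphate dehydrogenase (G6PDH2r) and
#' fructose-bisphosphatase (FBP); GED variants make Gnd reversible; RuBP
#' variants add phosphoribulokinase (PRK) and Rubisco (RBPC).
#'
#' @param name one of `"WT"`, `"GED_shunt"`, `"RuBP_shunt"`, `"GED_cycle"`,
#'   `"RuBP_cycle"`.
#' @return a list with elements `name`, `blocked`, `add_rubp`,
#'   `gnd_reversible`.
#' @export
variantSpec <- function(name = c("WT", "GED_shunt", "RuBP_shunt",
                                 "GED_cycle", "RuBP_cycle")) {
  name <- match.arg(name)
  shunt <- grepl("shunt$", name)
  list(name = name,
       blocked = if (shunt) .SHUNT_BLOCKS else character(),
       add_rubp = grepl("^RuBP", name),
       gnd_reversible = grepl("^GED", name))
}

#' Build a pathway variant of a model
#'
#' Applies a [variantSpec()] to a (curated) model: blocked reactions get
#' bounds (0, 0), PRK/RBPC are appended for RuBP variants (an error if
#' already present), and Gnd's lower bound is opened for GED variants.  Ids
#' are resolved through a small synonym table so genome-scale naming
#' (G6PDH2r) also hits the fixture's ZWF.
#'
#' @param net a [MetabolicNetwork-class].
#' @param spec a [variantSpec()] or variant name.
#' @return the modified copy.
#' @export
makeVariant <- function(net, spec) {
  if (is.character(spec)) spec <- variantSpec(spec)
  for (id in spec$blocked) {
    rid <- .resolveRxnId(net, id)
    if (is.na(rid)) {
      warning("variant ", spec$name, ": reaction ", id,
              " not in model, skipped", call. = FALSE)
      next
    }
    net <- .setBounds(net, rid, 0, 0)
  }
  if (spec$add_rubp) {
    net <- .addReaction(net, "PRK",
                        c(ru5p__D_c = -1, atp_c = -1, rb15bp_c = 1,
                          adp_c = 1, h_c = 1),
                        dg0 = -17.59, lb = 0, ub = 1000,
                        notes = "added for RuBP variant")
    net <- .addReaction(net, "RBPC",
                        c(rb15bp_c = -1, co2_c = -1, h2o_c = -1,
                          `3pg_c` = 2, h_c = 2),
                        dg0 = -34.59, lb = 0, ub = 1000,
                        notes = "added for RuBP variant")
  }
  if (spec$gnd_reversible) {
    rid <- .resolveRxnId(net, "GND")
    if (is.na(rid)) warning("variant ", spec$name, ": GND not in model",
                            call. = FALSE)
    else {
      ub <- reactions(net)$upper_bound[reactionIds(net) == rid]
      net <- .setBounds(net, rid, -1000, ub)
    }
  }
  net
}

.findExchange <- function(net, id) {
  ids <- reactionIds(net)
  if (id %in% ids && reactions(net)$is_exchange[ids == id]) return(id)
  if (id %in% metaboliteIds(net)) {
    S <- stoichiometry(net)
    ex <- ids[reactions(net)$is_exchange & !reactions(net)$is_pseudo]
    for (e in ex) if (S[id, e] != 0) return(e)
    return(NA_character_)
  }
  NA_character_
}

#' Maximal product yield of non-growing cells
#'
#' Solves the FBA linear program: maximize product secretion subject to
#' steady state, the stored flux bounds, the substrate uptake fixed at the
#' configured rate, the ATP maintenance flux fixed, free bidirectional CO2
#' exchange, and all other uptakes closed.  A missing product exchange is
#' auto-created (toy models are minimal).  Yield is product flux divided by
#' uptake; secretion fluxes above 1e-6 mmol/gDW/h are reported as
#' byproducts.
#'
#' @param net a curated, variant-modified [MetabolicNetwork-class].
#' @param config an [fbaConfig()].
#' @return a [YieldResult-class].
#' @export
maxProductYield <- function(net, config = fbaConfig()) {
  exSub <- .findExchange(net, config$substrate)
  if (is.na(exSub))
    stop("no exchange for substrate '", config$substrate, "'", call. = FALSE)
  if (config$h2_donor) {
    if (is.na(.resolveRxnId(net, "H2DH"))) {
      net <- .addReaction(net, "H2DH",
                          c(h2_c = -1, nad_c = -1, nadh_c = 1, h_c = 1),
                          dg0 = -18, lb = 0, ub = 1000,
                          notes = "hydrogen dehydrogenase (electron donor)")
    }
  }
  exProd <- .findExchange(net, config$product)
  if (is.na(exProd)) {
    target <- config$product
    if (!target %in% metaboliteIds(net))
      stop("product '", target, "' not in model", call. = FALSE)
    exProd <- paste0("EX_", target)
    net <- .addReaction(net, exProd, stats::setNames(-1, target),
                        lb = 0, ub = 1000, notes = "auto-created exchange")
  }
  if (!"ATPM" %in% reactionIds(net))
    stop("model has no ATPM maintenance reaction", call. = FALSE)
  r <- reactions(net)
  ## uptake policy: close all uptakes except substrate and the free species
  freeBases <- c("co2", "h", "h2o")
  if (config$aerobic) freeBases <- c(freeBases, "o2")
  for (k in which(r$is_exchange & !r$is_pseudo)) {
    id <- r$id[k]
    met <- names(reactionStoichiometry(net, id))
    if (id == exSub || .baseId(met) %in% freeBases) next
    if (config$h2_donor && .baseId(met) == "h2") {
      net <- .setBounds(net, id, -1000, 1000); next
    }
    net <- .setBounds(net, id, max(0, r$lower_bound[k]), r$upper_bound[k])
  }
  net <- .setBounds(net, exSub, -config$uptake, -config$uptake)
  net <- .setBounds(net, "ATPM", config$atpm, config$atpm)
  if (config$aerobic) {
    r2 <- reactions(net)
    for (id in r2$id[r2$oxygen_sensitive]) net <- .setBounds(net, id, 0, 0)
  }
  r <- reactions(net)
  S <- stoichiometry(net)
  touched <- Matrix::rowSums(abs(S)) > 0
  obj <- as.numeric(reactionIds(net) == exProd)
  prob <- lpProblem(obj = obj, A = S[touched, , drop = FALSE],
                    clb = rep(0, sum(touched)), cub = rep(0, sum(touched)),
                    vlb = r$lower_bound, vub = r$upper_bound, sense = "max")
  sol <- solveLp(prob, "highs")
  if (sol$status != "optimal") {
    stop("FBA infeasible for product '", exProd, "': binding constraints ",
         sprintf("uptake %s = %.3f, ATPM = %.3f", exSub, config$uptake,
                 config$atpm), call. = FALSE)
  }
  v <- stats::setNames(sol$x, reactionIds(net))
  secretion <- v[r$is_exchange & !r$is_pseudo & v > 1e-6]
  secretion <- secretion[names(secretion) != exProd]
  secretion <- secretion[!(.baseId(vapply(names(secretion), function(id)
    names(reactionStoichiometry(net, id)), character(1))) %in% c("h", "h2o"))]
  methods::new("YieldResult", yield = unname(v[exProd]) / config$uptake,
               relative_yield = NA_real_, byproducts = secretion,
               fluxes = v, product = exProd, substrate = exSub)
}

#' Relative yield table over variants and products
#'
#' Runs [maxProductYield()] for every (variant, product) pair and reports
#' yields absolute and relative to the WT reference of the same product
#' and configuration (the WT column is identically 1 where WT yield > 0;
#' a zero-WT product gets `NA` relative yield, absolute still reported).
#'
#' @param net a curated [MetabolicNetwork-class] (pre-variant).
#' @param variants character vector of variant names (WT is always added
#'   as the reference).
#' @param products character vector of product ids.
#' @param config an [fbaConfig()] (its `product` field is overridden).
#' @return data.frame with columns `variant`, `product`, `yield`,
#'   `relative_yield`, `byproducts`.
#' @export
relativeYieldTable <- function(net, variants = c("GED_shunt", "RuBP_shunt"),
                               products = c("EX_ac_e", "EX_lac__D_e",
                                            "EX_etoh_e"),
                               config = fbaConfig()) {
  allVars <- unique(c("WT", variants))
  rows <- list()
  wt <- stats::setNames(rep(NA_real_, length(products)), products)
  for (vn in allVars) {
    vnet <- makeVariant(net, vn)
    for (p in products) {
      cfg <- config; cfg$product <- p
      yr <- tryCatch(maxProductYield(vnet, cfg), error = function(e) NULL)
      y <- if (is.null(yr)) 0 else yr@yield
      if (vn == "WT") wt[p] <- y
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, product = p, yield = y,
        relative_yield = if (!is.na(wt[p]) && wt[p] > 1e-9) y / wt[p]
                         else NA_real_,
        byproducts = if (is.null(yr) || !length(yr@byproducts)) ""
                     else paste(sprintf("%s:%.3g", names(yr@byproducts),
                                        yr@byproducts), collapse = ","))
    }
  }
  do.call(rbind, rows)
}
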