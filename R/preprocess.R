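## Network preprocessing for pathway search: pruning to the cytosol,
## currency pseudo-reactions, carbon balance checks, oxygen-sensitivity
## filter.

.stoichAsList <- function(net) {
  S <- stoichiometry(net)
  lapply(stats::setNames(seq_len(ncol(S)), colnames(S)), function(j) {
    col <- S[, j]
    col[col != 0]
  })
}

.subsetReactions <- function(net, keep) {
  MetabolicNetwork(metabolites(net),
                   reactions(net)[keep, , drop = FALSE],
                   .stoichAsList(net)[reactions(net)$id[keep]],
                   provenance = net@provenance)
}

#' Restrict a network to strictly cytoplasmic chemistry
#'
#' Removes all exchange and transport reactions as well as any reaction
#' touching a non-cytosolic metabolite, leaving the strictly cytoplasmic
#' core used by the pathway search.  The input is not modified; the
#' metabolite table is kept intact.
#'
#' @param net a [MetabolicNetwork-class].
#' @param compartment compartment code that survives (default `"c"`).
#' @return the pruned network.
#' @export
pruneForSearch <- function(net, compartment = "c") {
  r <- reactions(net)
  S <- stoichiometry(net)
  cyto <- metabolites(net)$compartment == compartment
  touchesForeign <- Matrix::colSums(abs(S[!cyto, , drop = FALSE])) > 0
  keep <- (!(r$is_exchange | r$is_transport) | r$is_pseudo) & !touchesForeign
  .subsetReactions(net, keep)
}

#' Default currency specification for a network
#'
#' Regeneration pairs (ADP+Pi -> ATP, AMP+2Pi -> ATP, NAD+ -> NADH,
#' NADP+ -> NADPH) for the cofactor pairs present in the network, plus free
#' single-metabolite exchanges for the inorganic species (H+, H2O, O2, NH3)
#' that the network declares.  CO2 is deliberately absent: it is the counted
#' substrate of the search.
#'
#' @param net a [MetabolicNetwork-class].
#' @param compartment compartment suffix for the currency species.
#' @return a list with elements `regeneration` (named list of stoichiometry
#'   vectors) and `free` (metabolite ids to exchange freely).
#' @export
defaultCurrencySpec <- function(net, compartment = "c") {
  sfx <- function(x) paste0(x, "_", compartment)
  ids <- metaboliteIds(net)
  regen <- list()
  if (all(sfx(c("adp", "pi", "atp", "h2o")) %in% ids))
    regen$REGEN_ATP_ADP <- stats::setNames(c(-1, -1, 1, 1),
                                           sfx(c("adp", "pi", "atp", "h2o")))
  if (all(sfx(c("amp", "pi", "atp", "h2o")) %in% ids))
    regen$REGEN_ATP_AMP <- stats::setNames(c(-1, -2, 1, 2),
                                           sfx(c("amp", "pi", "atp", "h2o")))
  if (all(sfx(c("nad", "nadh")) %in% ids))
    regen$REGEN_NADH <- stats::setNames(c(-1, 1), sfx(c("nad", "nadh")))
  if (all(sfx(c("nadp", "nadph")) %in% ids))
    regen$REGEN_NADPH <- stats::setNames(c(-1, 1), sfx(c("nadp", "nadph")))
  free <- intersect(sfx(c("h", "h2o", "o2", "nh4")), ids)
  list(regeneration = regen, free = free)
}

#' Add currency pseudo-reactions
#'
#' Appends reversible pseudo-reactions that allow the free flow of energy
#' and electrons (ATP, NADH, NADPH regeneration) and of inorganic species
#' (free exchange of protons, water, oxygen, ammonia).  Pseudo-reactions are
#' flagged `is_pseudo` so they are excluded from reaction counts, driving
#' force constraints and reported pathway supports.
#'
#' @param net a [MetabolicNetwork-class] (typically pruned).
#' @param currencySpec a list as returned by [defaultCurrencySpec()]; an
#'   empty spec (`list()`) leaves the network unchanged.
#' @return the augmented network.
#' @export
addCurrencyExchanges <- function(net, currencySpec = defaultCurrencySpec(net)) {
  if (!length(currencySpec) ||
      (!length(currencySpec$regeneration) && !length(currencySpec$free))) {
    return(net)
  }
  ids <- metaboliteIds(net)
  named <- unique(c(unlist(lapply(currencySpec$regeneration, names)),
                    currencySpec$free))
  missing <- setdiff(named, ids)
  if (length(missing))
    stop("currency species not in network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sto <- .stoichAsList(net)
  rows <- list()
  for (nm in names(currencySpec$regeneration)) {
    id <- paste0("PSEUDO_", nm)
    sto[[id]] <- currencySpec$regeneration[[nm]]
    rows[[id]] <- data.frame(id = id, dg0_prime = NA_real_,
                             lower_bound = -1000, upper_bound = 1000,
                             oxygen_sensitive = FALSE, is_exchange = FALSE,
                             is_transport = FALSE, is_pseudo = TRUE,
                             notes = "currency regeneration pseudo-reaction")
  }
  for (sp in currencySpec$free) {
    id <- paste0("PSEUDO_EX_", sp)
    sto[[id]] <- stats::setNames(-1, sp)
    rows[[id]] <- data.frame(id = id, dg0_prime = NA_real_,
                             lower_bound = -1000, upper_bound = 1000,
                             oxygen_sensitive = FALSE, is_exchange = TRUE,
                             is_transport = FALSE, is_pseudo = TRUE,
                             notes = "free currency exchange pseudo-reaction")
  }
  newIds <- names(rows)
  clash <- intersect(newIds, reactions(net)$id)
  if (length(clash)) {
    ## idempotence: silently skip pseudo-reactions that are already present
    newIds <- setdiff(newIds, clash)
    if (!length(newIds)) return(net)
  }
  rxns <- rbind(reactions(net), do.call(rbind, rows[newIds]))
  MetabolicNetwork(metabolites(net), rxns, sto[rxns$id],
                   provenance = net@provenance)
}

#' Check elemental carbon balance of a network
#'
#' Computes the signed sum of coefficient times carbon count over every
#' non-exchange, non-pseudo reaction and returns the ids of reactions whose
#' carbon does not balance.
#'
#' @param net a [MetabolicNetwork-class].
#' @param tol absolute tolerance on the carbon sum.
#' @return character vector of violating reaction ids (empty when balanced).
#' @export
carbonBalanceCheck <- function(net, tol = 1e-9) {
  m <- metabolites(net); r <- reactions(net); S <- stoichiometry(net)
  check <- !r$is_exchange & !r$is_pseudo
  if (!any(check)) return(character())
  Ssub <- S[, check, drop = FALSE]
  touched <- Matrix::rowSums(abs(Ssub)) > 0
  unknown <- m$id[touched & is.na(m$carbons)]
  if (length(unknown))
    stop("unknown carbon counts for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  carbons <- ifelse(is.na(m$carbons), 0, m$carbons)
  sums <- as.numeric(carbons %*% Ssub)
  r$id[check][abs(sums) > tol]
}

#' Remove oxygen-sensitive reactions
#'
#' Drops every reaction flagged `oxygen_sensitive` (in the organism studied
#' here: pyruvate formate lyase and 2-oxobutanoate formate lyase).  Used to
#' ask which pathways survive strictly aerobic conditions.
#'
#' @param net a [MetabolicNetwork-class].
#' @return a copy without the flagged reactions.
#' @export
removeOxygenSensitive <- function(net) {
  .subsetReactions(net, !reactions(net)$oxygen_sensitive)
}
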