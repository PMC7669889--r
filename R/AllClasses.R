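#' @import methods
#' @importFrom Matrix Matrix sparseMatrix colSums rowSums t
NULL

## ---------------------------------------------------------------------------
## MetabolicNetwork
## ---------------------------------------------------------------------------

#' MetabolicNetwork: metabolites, reactions and the stoichiometric matrix
#'
#' The central container of the package.  `metabolites` and `reactions` are
#' annotation tables; `stoichiometry` is the sparse stoichiometric matrix S
#' (metabolites x reactions, negative = consumed).  Currency metabolites
#' (ATP/NAD(P)H/inorganics) are flagged so they can be supplied freely during
#' pathway search; pseudo-reactions added for that purpose carry `is_pseudo`
#' and are excluded from reaction counts and thermodynamic constraints.
#'
#' @slot metabolites data.frame with columns `id`, `name`, `carbons`,
#'   `compartment`, `is_currency`, `fixed_conc` (molar, NA = free).
#' @slot reactions data.frame with columns `id`, `dg0_prime` (kJ/mol,
#'   transformed standard reaction Gibbs energy in the written direction),
#'   `lower_bound`, `upper_bound` (flux bounds, mmol/gDW/h semantics, used by
#'   FBA only), `oxygen_sensitive`, `is_exchange`, `is_transport`,
#'   `is_pseudo`, `notes`.
#' @slot stoichiometry sparse `dgCMatrix`, rows = metabolite ids, columns =
#'   reaction ids.
#' @slot provenance free-text origin of the model.
#' @export
setClass("MetabolicNetwork",
         slots = c(metabolites = "data.frame",
                   reactions = "data.frame",
                   stoichiometry = "Matrix",
                   provenance = "character"))

.MET_COLS <- c("id", "name", "carbons", "compartment", "is_currency",
               "fixed_conc")
.RXN_COLS <- c("id", "dg0_prime", "lower_bound", "upper_bound",
               "oxygen_sensitive", "is_exchange", "is_transport", "is_pseudo",
               "notes")

setValidity("MetabolicNetwork", function(object) {
  m <- object@metabolites; r <- object@reactions; S <- object@stoichiometry
  msgs <- character()
  if (!all(.MET_COLS %in% names(m)))
    msgs <- c(msgs, paste("metabolites must have columns:",
                          paste(.MET_COLS, collapse = ", ")))
  if (!all(.RXN_COLS %in% names(r)))
    msgs <- c(msgs, paste("reactions must have columns:",
                          paste(.RXN_COLS, collapse = ", ")))
  if (length(msgs)) return(msgs)
  if (anyDuplicated(m$id))
    msgs <- c(msgs, paste("duplicate metabolite ids:",
                          paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  if (anyDuplicated(r$id))
    msgs <- c(msgs, paste("duplicate reaction ids:",
                          paste(unique(r$id[duplicated(r$id)]), collapse = ", ")))
  if (!identical(dim(S), c(nrow(m), nrow(r))))
    msgs <- c(msgs, "stoichiometry dimensions do not match tables")
  else {
    rn <- if (is.null(rownames(S))) character(nrow(S)) else rownames(S)
    cn <- if (is.null(colnames(S))) character(ncol(S)) else colnames(S)
    if (!identical(rn, m$id) || !identical(cn, r$id))
      msgs <- c(msgs, "stoichiometry dimnames must equal metabolite/reaction ids")
    if (nrow(r) > 0) {
      empty <- Matrix::colSums(S != 0) == 0
      if (any(empty))
        msgs <- c(msgs, paste("reactions with empty net stoichiometry:",
                              paste(r$id[empty], collapse = ", ")))
      nTouched <- Matrix::colSums(S != 0)
      bad <- r$is_exchange & !r$is_pseudo & nTouched != 1
      if (any(bad))
        msgs <- c(msgs, paste("exchange reactions must touch exactly one metabolite:",
                              paste(r$id[bad], collapse = ", ")))
    }
  }
  if (any(!is.na(m$carbons) & m$carbons < 0))
    msgs <- c(msgs, "carbon counts must be >= 0")
  if (length(msgs)) msgs else TRUE
})

.emptyMetTable <- function() {
  data.frame(id = character(), name = character(), carbons = integer(),
             compartment = character(), is_currency = logical(),
             fixed_conc = numeric(), stringsAsFactors = FALSE)
}

.emptyRxnTable <- function() {
  data.frame(id = character(), dg0_prime = numeric(), lower_bound = numeric(),
             upper_bound = numeric(), oxygen_sensitive = logical(),
             is_exchange = logical(), is_transport = logical(),
             is_pseudo = logical(), notes = character(),
             stringsAsFactors = FALSE)
}

#' Construct a MetabolicNetwork
#'
#' @param metabolites data.frame with at least an `id` column; missing
#'   annotation columns are filled with defaults.
#' @param reactions data.frame with at least an `id` column.
#' @param stoichiometry either a (sparse) matrix, or a named list mapping
#'   reaction id to a named numeric vector of signed coefficients.
#' @param provenance free-text origin.
#' @return a validated [MetabolicNetwork-class] object.
#' @export
#' @examples
#' net <- MetabolicNetwork(
#'   metabolites = data.frame(id = c("a_c", "b_c"), carbons = c(1L, 1L)),
#'   reactions = data.frame(id = "R1"),
#'   stoichiometry = list(R1 = c(a_c = -1, b_c = 1)))
MetabolicNetwork <- function(metabolites = .emptyMetTable(),
                             reactions = .emptyRxnTable(),
                             stoichiometry = NULL,
                             provenance = "constructed in R") {
  metabolites <- .fillMetCols(as.data.frame(metabolites))
  reactions <- .fillRxnCols(as.data.frame(reactions))
  if (is.list(stoichiometry) && !is.matrix(stoichiometry) &&
      !methods::is(stoichiometry, "Matrix")) {
    S <- .stoichFromList(stoichiometry, metabolites$id, reactions$id)
  } else if (is.null(stoichiometry)) {
    S <- Matrix::Matrix(0, nrow(metabolites), nrow(reactions), sparse = TRUE,
                        dimnames = list(metabolites$id, reactions$id))
  } else {
    S <- Matrix::Matrix(stoichiometry, sparse = TRUE)
    dimnames(S) <- list(metabolites$id, reactions$id)
  }
  methods::new("MetabolicNetwork", metabolites = metabolites,
               reactions = reactions,
               stoichiometry = methods::as(S, "CsparseMatrix"),
               provenance = provenance)
}

.fillMetCols <- function(m) {
  stopifnot("id" %in% names(m))
  n <- nrow(m)
  if (is.null(m$name)) m$name <- m$id
  if (is.null(m$carbons)) m$carbons <- NA_integer_
  m$carbons <- as.integer(m$carbons)
  if (is.null(m$compartment))
    m$compartment <- sub("^.*_([a-z]+)$", "\\1", m$id)
  if (is.null(m$is_currency)) m$is_currency <- FALSE
  if (is.null(m$fixed_conc)) m$fixed_conc <- NA_real_
  rownames(m) <- NULL
  m[, .MET_COLS]
}

.fillRxnCols <- function(r) {
  stopifnot("id" %in% names(r))
  if (is.null(r$dg0_prime)) r$dg0_prime <- NA_real_
  if (is.null(r$lower_bound)) r$lower_bound <- -1000
  if (is.null(r$upper_bound)) r$upper_bound <- 1000
  if (is.null(r$oxygen_sensitive)) r$oxygen_sensitive <- FALSE
  if (is.null(r$is_exchange)) r$is_exchange <- grepl("^EX_", r$id)
  if (is.null(r$is_transport)) r$is_transport <- FALSE
  if (is.null(r$is_pseudo)) r$is_pseudo <- FALSE
  if (is.null(r$notes)) r$notes <- ""
  rownames(r) <- NULL
  r[, .RXN_COLS]
}

.stoichFromList <- function(lst, metIds, rxnIds) {
  stopifnot(identical(sort(names(lst)), sort(rxnIds)))
  i <- integer(); j <- integer(); x <- numeric()
  for (k in seq_along(rxnIds)) {
    sto <- lst[[rxnIds[k]]]
    sto <- sto[sto != 0]
    if (!length(sto))
      stop("reaction '", rxnIds[k], "' has empty net stoichiometry",
           call. = FALSE)
    unknown <- setdiff(names(sto), metIds)
    if (length(unknown))
      stop("reaction '", rxnIds[k], "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    i <- c(i, match(names(sto), metIds))
    j <- c(j, rep(k, length(sto)))
    x <- c(x, unname(sto))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(metIds), length(rxnIds)),
                       dimnames = list(metIds, rxnIds))
}

## ---------------------------------------------------------------------------
## Thermodynamic parameter objects
## ---------------------------------------------------------------------------

#' Thermodynamic parameters
#'
#' Temperature defaults to 298.15 K, the convention under which the vendored
#' transformed Gibbs energies were derived; `RT` is derived as
#' 0.008314 * temperature (kJ/mol).  `ph` and `ionic_strength` are metadata:
#' the dG'0 inputs are already pH/ionic-strength transformed.
#' `henry_co2` (M/bar) converts CO2 partial pressure to its dissolved
#' concentration.
#'
#' @slot temperature K
#' @slot ph unitless (metadata)
#' @slot ionic_strength M (metadata)
#' @slot henry_co2 M/bar
#' @export
setClass("ThermoParams",
         slots = c(temperature = "numeric", ph = "numeric",
                   ionic_strength = "numeric", henry_co2 = "numeric"))

#' @param temperature K
#' @param ph unitless
#' @param ionic_strength M
#' @param henry_co2 M/bar (default 0.0338, CO2 at 25 C)
#' @rdname ThermoParams-class
#' @export
thermoParams <- function(temperature = 298.15, ph = 7.5,
                         ionic_strength = 0.25, henry_co2 = 0.0338) {
  methods::new("ThermoParams", temperature = temperature, ph = ph,
               ionic_strength = ionic_strength, henry_co2 = henry_co2)
}

#' Gas constant times temperature, kJ/mol
#' @param params a [ThermoParams-class] object.
#' @export
rtOf <- function(params) 0.008314 * params@temperature

#' Metabolite concentration bounds for driving-force optimisation
#'
#' Default physiological range 1 uM - 10 mM; per-metabolite overrides; fixed
#' species (e.g. dissolved CO2 pinned at the Henry-law level of a chosen
#' partial pressure) are excluded from optimisation.  Water and protons never
#' enter concentration terms.
#'
#' @slot default_lb,default_ub molar
#' @slot overrides named list of `c(lb, ub)` molar pairs
#' @slot fixed named numeric, molar
#' @export
setClass("ConcentrationBounds",
         slots = c(default_lb = "numeric", default_ub = "numeric",
                   overrides = "list", fixed = "numeric"))

setValidity("ConcentrationBounds", function(object) {
  msgs <- character()
  if (!(object@default_lb > 0 && object@default_lb <= object@default_ub))
    msgs <- c(msgs, "need 0 < default_lb <= default_ub")
  for (id in names(object@overrides)) {
    o <- object@overrides[[id]]
    if (length(o) != 2 || !(o[1] > 0 && o[1] <= o[2]))
      msgs <- c(msgs, paste0("invalid override for ", id))
  }
  both <- intersect(names(object@fixed), names(object@overrides))
  if (length(both))
    msgs <- c(msgs, paste("fixed species may not also carry bounds:",
                          paste(both, collapse = ", ")))
  if (any(object@fixed <= 0)) msgs <- c(msgs, "fixed concentrations must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @param default_lb,default_ub molar bounds applied to every free metabolite.
#' @param overrides named list of `c(lb, ub)` molar pairs.
#' @param fixed named numeric of pinned molar concentrations.
#' @rdname ConcentrationBounds-class
#' @export
concentrationBounds <- function(default_lb = 1e-6, default_ub = 1e-2,
                                overrides = list(), fixed = numeric()) {
  methods::new("ConcentrationBounds", default_lb = default_lb,
               default_ub = default_ub, overrides = overrides, fixed = fixed)
}

## ---------------------------------------------------------------------------
## Results
## ---------------------------------------------------------------------------

#' Result of a Max-min Driving Force optimisation
#'
#' @slot mdf kJ/mol, the optimal max-min driving force B.
#' @slot logConcentrations named numeric, ln(molar) at the optimum.
#' @slot reactionDgPrime named numeric, transformed reaction Gibbs energy
#'   (kJ/mol) of each constrained reaction at the optimum, in the direction
#'   of pathway flux.
#' @slot bottlenecks ids of reactions whose driving force equals B.
#' @export
setClass("DrivingForceResult",
         slots = c(mdf = "numeric", logConcentrations = "numeric",
                   reactionDgPrime = "numeric", bottlenecks = "character"))

#' A candidate pathway returned by the search
#'
#' @slot support data.frame with columns `id` and `direction` (+1 forward,
#'   -1 backward relative to the written reaction), pseudo-reactions excluded.
#' @slot fluxes named numeric, signed flux per reaction (including pseudo
#'   fluxes), scaled to 1 mole of net product.
#' @slot netConversion named numeric, net moles per mole product over
#'   non-free metabolites.
#' @slot mdf kJ/mol (exact-LP value for the support).
#' @slot nReactions integer, `nrow(support)`.
#' @export
setClass("CandidatePathway",
         slots = c(support = "data.frame", fluxes = "numeric",
                   netConversion = "numeric", mdf = "numeric",
                   nReactions = "integer"))

#' An FBA yield result
#'
#' @slot yield mol product per mol substrate.
#' @slot relative_yield ratio to the wild-type reference (NA if undefined).
#' @slot byproducts named numeric, secretion fluxes (mmol/gDW/h) above the
#'   reporting threshold, excluding the product itself.
#' @slot fluxes named numeric, the full optimal flux vector (mmol/gDW/h).
#' @slot product,substrate exchange metabolite ids.
#' @export
setClass("YieldResult",
         slots = c(yield = "numeric", relative_yield = "numeric",
                   byproducts = "numeric", fluxes = "numeric",
                   product = "character", substrate = "character"))
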