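## Accessors and show methods.

#' @describeIn MetabolicNetwork-class metabolite annotation table
#' @param object,x a `MetabolicNetwork`.
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @rdname MetabolicNetwork-class
#' @export
setMethod("metabolites", "MetabolicNetwork", function(object) object@metabolites)

#' @describeIn MetabolicNetwork-class reaction annotation table
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname MetabolicNetwork-class
#' @export
setMethod("reactions", "MetabolicNetwork", function(object) object@reactions)

#' @describeIn MetabolicNetwork-class sparse stoichiometric matrix S
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @rdname MetabolicNetwork-class
#' @export
setMethod("stoichiometry", "MetabolicNetwork",
          function(object) object@stoichiometry)

#' @describeIn MetabolicNetwork-class reaction ids
#' @export
reactionIds <- function(object) object@reactions$id

#' @describeIn MetabolicNetwork-class metabolite ids
#' @export
metaboliteIds <- function(object) object@metabolites$id

#' @describeIn MetabolicNetwork-class signed stoichiometry of one reaction as
#'   a named numeric vector
#' @param reaction a reaction id.
#' @export
reactionStoichiometry <- function(object, reaction) {
  stopifnot(reaction %in% object@reactions$id)
  col <- object@stoichiometry[, reaction]
  col[col != 0]
}

setMethod("show", "MetabolicNetwork", function(object) {
  r <- object@reactions
  cat("MetabolicNetwork:", nrow(object@metabolites), "metabolites,",
      nrow(r), "reactions\n")
  cat("  exchange:", sum(r$is_exchange & !r$is_pseudo),
      " transport:", sum(r$is_transport),
      " pseudo:", sum(r$is_pseudo),
      " with dG'0:", sum(!is.na(r$dg0_prime)), "\n")
  cat("  provenance:", object@provenance, "\n")
})

#' @describeIn DrivingForceResult-class the optimal max-min driving force B
#'   (kJ/mol)
#' @param object a result object.
#' @export
setGeneric("mdf", function(object) standardGeneric("mdf"))

#' @rdname DrivingForceResult-class
#' @export
setMethod("mdf", "DrivingForceResult", function(object) object@mdf)

#' @rdname CandidatePathway-class
#' @export
setMethod("mdf", "CandidatePathway", function(object) object@mdf)

#' @describeIn CandidatePathway-class directed support (data.frame of
#'   reaction id and direction)
#' @param object a `CandidatePathway`.
#' @export
pathwaySupport <- function(object) object@support

#' @describeIn CandidatePathway-class signed fluxes scaled to one mole of
#'   product
#' @export
pathwayFluxes <- function(object) object@fluxes

#' @describeIn CandidatePathway-class number of (non-pseudo) reactions
#' @export
pathwaySize <- function(object) object@nReactions

setMethod("show", "DrivingForceResult", function(object) {
  cat(sprintf("DrivingForceResult: MDF = %.3f kJ/mol over %d reactions\n",
              object@mdf, length(object@reactionDgPrime)))
  if (length(object@bottlenecks))
    cat("  bottleneck(s):", paste(object@bottlenecks, collapse = ", "), "\n")
})

setMethod("show", "CandidatePathway", function(object) {
  dirMark <- ifelse(object@support$direction > 0, "", " (rev)")
  cat(sprintf("CandidatePathway: %d reactions, MDF = %.3f kJ/mol\n",
              object@nReactions, object@mdf))
  cat("  support:", paste0(object@support$id, dirMark, collapse = ", "), "\n")
  nc <- object@netConversion
  cat("  net conversion:",
      paste(sprintf("%s: %+g", names(nc), nc), collapse = ", "), "\n")
})

setMethod("show", "YieldResult", function(object) {
  cat(sprintf("YieldResult: %s from %s, yield %.4f mol/mol (relative %.3f)\n",
              object@product, object@substrate, object@yield,
              object@relative_yield))
  if (length(object@byproducts))
    cat("  byproducts:",
        paste(sprintf("%s %.3f", names(object@byproducts), object@byproducts),
              collapse = ", "), "\n")
})
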