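## Transformed Gibbs-energy arithmetic, Henry's-law CO2 conversions and the
## Max-min Driving Force linear program.
##
## Conventions: dG'0 values are transformed standard reaction Gibbs energies
## (pH/ionic-strength already folded in), so water and protons never
## contribute concentration terms.  Concentrations enter as natural
## logarithms of molar values.

.THERMO_EXCLUDED <- c("h", "h2o")  # base ids without concentration terms

.isThermoExcluded <- function(ids) .baseId(ids) %in% .THERMO_EXCLUDED

## fixed concentrations: explicit bounds@fixed wins over the metabolite
## table's fixed_conc column
.fixedConcentrations <- function(net, bounds) {
  m <- metabolites(net)
  fixed <- stats::setNames(m$fixed_conc[!is.na(m$fixed_conc)],
                           m$id[!is.na(m$fixed_conc)])
  fixed[names(bounds@fixed)] <- bounds@fixed
  fixed
}

#' Transformed reaction Gibbs energy at reference concentrations
#'
#' Evaluates dG' = dG'0 + RT * sum_i s_i ln(c_i) for one reaction, where the
#' sum runs over all participants except water and protons.  Metabolites with
#' a fixed concentration (notably dissolved CO2 pinned at the Henry-law level
#' of an elevated partial pressure) use that value; every other participant
#' uses `reference` (default 1 mM, the "physiological standard" convention).
#'
#' @param net a [MetabolicNetwork-class].
#' @param reaction a reaction id in `net`.
#' @param params a [ThermoParams-class].
#' @param reference either a single molar concentration applied to all
#'   non-fixed participants (default 1e-3) or a named molar vector covering
#'   them.
#' @return dG' in kJ/mol for the reaction as written.
#' @export
#' @examples
#' net <- buildCoreModel()
#' transformDg(net, "GND")   # reductive carboxylation is nearly reversible
transformDg <- function(net, reaction, params = thermoParams(),
                        reference = 1e-3) {
  r <- reactions(net)
  if (!reaction %in% r$id) stop("unknown reaction: ", reaction, call. = FALSE)
  dg0 <- r$dg0_prime[r$id == reaction]
  if (is.na(dg0))
    stop("reaction '", reaction, "' has no dG'0", call. = FALSE)
  sto <- reactionStoichiometry(net, reaction)
  sto <- sto[!.isThermoExcluded(names(sto))]
  fixed <- .fixedConcentrations(net, concentrationBounds())
  conc <- numeric(0)
  if (length(reference) == 1 && is.null(names(reference))) {
    conc <- stats::setNames(rep(reference, length(sto)), names(sto))
  } else {
    conc <- reference[names(sto)]
    names(conc) <- names(sto)
  }
  conc[names(sto) %in% names(fixed)] <-
    fixed[names(sto)[names(sto) %in% names(fixed)]]
  if (anyNA(conc))
    stop("missing reference concentration for: ",
         paste(names(sto)[is.na(conc)], collapse = ", "), call. = FALSE)
  dg0 + rtOf(params) * sum(sto * log(conc))
}

#' Equilibrium constant from a transformed Gibbs energy (and back)
#'
#' `keqFromDg` computes Keq = exp(-dG'0 / RT); `dgFromKeq` is the exact
#' inverse.
#'
#' @param dg0 kJ/mol.
#' @param keq unitless equilibrium constant.
#' @param params a [ThermoParams-class].
#' @return unitless Keq, or kJ/mol.
#' @export
keqFromDg <- function(dg0, params = thermoParams()) exp(-dg0 / rtOf(params))

#' @rdname keqFromDg
#' @export
dgFromKeq <- function(keq, params = thermoParams()) -rtOf(params) * log(keq)

#' Henry's-law conversion between CO2 partial pressure and dissolved CO2
#'
#' `co2PressureToConc` maps a partial pressure in mbar to the dissolved
#' molar concentration (c = H * p); `co2ConcToPressure` is the exact
#' inverse; `co2HeadspacePercent` expresses a dissolved concentration as the
#' equivalent percent CO2 of the headspace at ambient pressure.
#'
#' @param p partial pressure, mbar.
#' @param conc dissolved concentration, molar.
#' @param params a [ThermoParams-class] (supplies the Henry constant,
#'   M/bar).
#' @param ambient_mbar ambient pressure (default 1013.25 mbar).
#' @return molar concentration, mbar, or percent.
#' @export
#' @examples
#' co2PressureToConc(200)                # approx 6.8 mM at 20% CO2
#' co2HeadspacePercent(0.9e-3)           # KM(CO2) approx 3% headspace
co2PressureToConc <- function(p, params = thermoParams()) {
  if (any(p < 0)) stop("negative partial pressure", call. = FALSE)
  params@henry_co2 * p / 1000
}

#' @rdname co2PressureToConc
#' @export
co2ConcToPressure <- function(conc, params = thermoParams()) {
  if (any(conc < 0)) stop("negative concentration", call. = FALSE)
  1000 * conc / params@henry_co2
}

#' @rdname co2PressureToConc
#' @export
co2HeadspacePercent <- function(conc, params = thermoParams(),
                                ambient_mbar = 1013.25) {
  100 * co2ConcToPressure(conc, params) / ambient_mbar
}

## normalize a pathway argument to a data.frame(id, direction)
.asSupport <- function(support) {
  if (methods::is(support, "CandidatePathway")) return(support@support)
  if (is.character(support))
    return(data.frame(id = support, direction = rep(1, length(support))))
  stopifnot(is.data.frame(support), all(c("id", "direction") %in% names(support)))
  support
}

#' Max-min Driving Force of a pathway
#'
#' Solves the MDF linear program: maximize B such that every pathway
#' reaction, taken in its direction of flux, has driving force
#' -dG' = -(dG'0 + RT * sum_j S_j x_j) >= B, with log-concentrations x
#' confined to a physiological range.  Fixed species (dissolved CO2 at its
#' set partial pressure; O2/ammonia at defaults) are pinned; water and
#' protons are excluded; currency pseudo-reactions are never constrained.
#'
#' @param net a [MetabolicNetwork-class] carrying dG'0 values.
#' @param support pathway: a character vector of reaction ids (forward), a
#'   data.frame with columns `id` and `direction` (+1/-1), or a
#'   [CandidatePathway-class].
#' @param bounds a [ConcentrationBounds-class].
#' @param params a [ThermoParams-class].
#' @param dg0 optional named vector overriding the network's dG'0 values.
#' @param engine LP engine, see [solveLp()].
#' @return a [DrivingForceResult-class].
#' @export
computeMdf <- function(net, support, bounds = concentrationBounds(),
                       params = thermoParams(), dg0 = NULL,
                       engine = c("highs", "simplex")) {
  engine <- match.arg(engine)
  sup <- .asSupport(support)
  r <- reactions(net)
  stopifnot(all(sup$id %in% r$id), all(sup$direction %in% c(-1, 1)))
  sup <- sup[!r$is_pseudo[match(sup$id, r$id)], , drop = FALSE]
  if (nrow(sup) == 0)
    stop("no constraining reactions: MDF is unbounded", call. = FALSE)
  dgAll <- stats::setNames(r$dg0_prime, r$id)
  if (!is.null(dg0)) dgAll[names(dg0)] <- dg0
  missing <- sup$id[is.na(dgAll[sup$id])]
  if (length(missing))
    stop("missing dG'0 for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  S <- stoichiometry(net)
  fixed <- .fixedConcentrations(net, bounds)
  RT <- rtOf(params)

  participants <- unique(unlist(lapply(sup$id, function(id)
    names(reactionStoichiometry(net, id)))))
  participants <- participants[!.isThermoExcluded(participants)]
  freeMets <- setdiff(participants, names(fixed))
  nx <- length(freeMets)

  lb <- rep(log(bounds@default_lb), nx)
  ub <- rep(log(bounds@default_ub), nx)
  names(lb) <- names(ub) <- freeMets
  for (id in intersect(names(bounds@overrides), freeMets)) {
    lb[id] <- log(bounds@overrides[[id]][1])
    ub[id] <- log(bounds@overrides[[id]][2])
  }
  if (any(lb > ub)) stop("infeasible concentration bounds", call. = FALSE)

  ## variables: x (nx), B (1); constraint per supported reaction:
  ##   RT * sum_j d*S_j x_j + B <= -const_r
  nr <- nrow(sup)
  Ai <- integer(); Aj <- integer(); Ax <- numeric()
  cub <- numeric(nr)
  for (k in seq_len(nr)) {
    sto <- reactionStoichiometry(net, sup$id[k]) * sup$direction[k]
    sto <- sto[!.isThermoExcluded(names(sto))]
    const <- dgAll[[sup$id[k]]] * sup$direction[k]
    fixedPart <- intersect(names(sto), names(fixed))
    if (length(fixedPart))
      const <- const + RT * sum(sto[fixedPart] * log(fixed[fixedPart]))
    freePart <- setdiff(names(sto), fixedPart)
    if (length(freePart)) {
      Ai <- c(Ai, rep(k, length(freePart)))
      Aj <- c(Aj, match(freePart, freeMets))
      Ax <- c(Ax, RT * unname(sto[freePart]))
    }
    Ai <- c(Ai, k); Aj <- c(Aj, nx + 1L); Ax <- c(Ax, 1)
    cub[k] <- -const
  }
  A <- Matrix::sparseMatrix(i = Ai, j = Aj, x = Ax, dims = c(nr, nx + 1L))
  prob <- lpProblem(obj = c(rep(0, nx), 1), A = A,
                    clb = rep(-Inf, nr), cub = cub,
                    vlb = c(lb, -Inf), vub = c(ub, Inf), sense = "max")
  sol <- solveLp(prob, engine)
  if (sol$status != "optimal")
    stop("MDF optimisation failed: ", sol$status, call. = FALSE)
  x <- stats::setNames(sol$x[seq_len(nx)], freeMets)
  B <- sol$x[nx + 1L]
  logc <- c(x, log(fixed[intersect(names(fixed), participants)]))
  dgPrime <- vapply(seq_len(nr), function(k) {
    sto <- reactionStoichiometry(net, sup$id[k]) * sup$direction[k]
    sto <- sto[!.isThermoExcluded(names(sto))]
    dgAll[[sup$id[k]]] * sup$direction[k] + RT * sum(sto * logc[names(sto)])
  }, numeric(1))
  names(dgPrime) <- sup$id
  methods::new("DrivingForceResult", mdf = B,
               logConcentrations = logc,
               reactionDgPrime = dgPrime,
               bottlenecks = sup$id[-dgPrime <= B + 1e-6])
}
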