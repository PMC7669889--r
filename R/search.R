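## Thermodynamics-constrained MILP enumeration of carbon-fixation pathways.
##
## Every reversible reaction is split into forward/backward arcs, each with a
## binary activity indicator z and a flux 0 <= v <= V*z.  Steady state is
## imposed on all metabolites except the substrate/product (net conversion,
## by default 3 CO2 -> 1 pyruvate) and the species balanced by currency
## pseudo-reactions.  Driving-force constraints are linked to the indicators
## by big-M, a positive max-min driving force B is required, and the
## objective maximizes B (in units of RT) minus a weighted reaction count.
## Integer cuts iterate the solution space; each solution is re-certified
## with the exact MDF linear program.

#' Define a pathway search query
#'
#' @param substrate metabolite id consumed (default dissolved CO2).
#' @param substrateMoles moles consumed per `productMoles` of product.
#' @param product metabolite id produced.
#' @param productMoles moles produced (fluxes are reported at this scale).
#' @return a named list used by [enumeratePathways()].
#' @export
pathwayQuery <- function(substrate = "co2_c", substrateMoles = 3,
                         product = "pyr_c", productMoles = 1) {
  stopifnot(substrate != product, substrateMoles > 0, productMoles > 0)
  list(substrate = substrate, substrateMoles = substrateMoles,
       product = product, productMoles = productMoles)
}

.arcKey <- function(support) {
  support <- .asSupport(support)
  paste(sort(paste0(support$id, ":", support$direction)), collapse = ";")
}

## prune + currency-augment unless the caller already did
.prepareForSearch <- function(net) {
  r <- reactions(net)
  if (any((r$is_exchange | r$is_transport) & !r$is_pseudo)) {
    net <- pruneForSearch(net)
  }
  if (!any(reactions(net)$is_pseudo)) {
    spec <- defaultCurrencySpec(net)
    if (length(spec$regeneration) || length(spec$free)) {
      net <- addCurrencyExchanges(net, spec)
    }
  }
  net
}

.buildSearchMilp <- function(net, query, bounds, params, w, bigM, fluxCap) {
  r <- reactions(net)
  S <- stoichiometry(net)
  RT <- rtOf(params)
  elig <- which(!r$is_pseudo)
  pseudo <- which(r$is_pseudo)
  nE <- length(elig); nP <- length(pseudo)
  missing <- r$id[elig][is.na(r$dg0_prime[elig])]
  if (length(missing))
    stop("no dG'0 for candidate reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  fixed <- .fixedConcentrations(net, bounds)
  metIds <- metaboliteIds(net)
  thermoMets <- metIds[!.isThermoExcluded(metIds) & !(metIds %in% names(fixed))]
  nx <- length(thermoMets)
  ## variable layout: vf(nE) vb(nE) vp(nP) zf(nE) zb(nE) x(nx) B
  iVF <- seq_len(nE); iVB <- nE + seq_len(nE); iVP <- 2L * nE + seq_len(nP)
  iZF <- 2L * nE + nP + seq_len(nE); iZB <- 2L * nE + nP + nE + seq_len(nE)
  iX <- 2L * nE + nP + 2L * nE + seq_len(nx)
  iB <- 2L * nE + nP + 2L * nE + nx + 1L
  nv <- iB

  Ai <- integer(); Aj <- integer(); Ax <- numeric()
  clb <- numeric(); cub <- numeric()
  addTriplets <- function(row, cols, vals) {
    Ai <<- c(Ai, rep(row, length(cols))); Aj <<- c(Aj, cols); Ax <<- c(Ax, vals)
  }
  nrow <- 0L
  newRow <- function(lo, hi) {
    nrow <<- nrow + 1L; clb[nrow] <<- lo; cub[nrow] <<- hi; nrow
  }
  ## mass balance
  b <- stats::setNames(rep(0, length(metIds)), metIds)
  b[query$substrate] <- -query$substrateMoles
  b[query$product] <- query$productMoles
  St <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  byMet <- split(data.frame(j = St@j + 1L, x = St@x), St@i + 1L)
  for (mi in seq_along(metIds)) {
    ent <- byMet[[as.character(mi)]]
    if (is.null(ent) && b[mi] == 0) next
    row <- newRow(b[[mi]], b[[mi]])
    if (!is.null(ent)) {
      for (k in seq_len(nrow(ent))) {
        j <- ent$j[k]; x <- ent$x[k]
        if (j %in% elig) {
          e <- match(j, elig)
          addTriplets(row, c(iVF[e], iVB[e]), c(x, -x))
        } else {
          p <- match(j, pseudo)
          addTriplets(row, iVP[p], x)
        }
      }
    }
  }
  ## flux-indicator coupling and direction exclusivity
  for (e in seq_len(nE)) {
    row <- newRow(-Inf, 0); addTriplets(row, c(iVF[e], iZF[e]), c(1, -fluxCap))
    row <- newRow(-Inf, 0); addTriplets(row, c(iVB[e], iZB[e]), c(1, -fluxCap))
    row <- newRow(-Inf, 1); addTriplets(row, c(iZF[e], iZB[e]), c(1, 1))
  }
  ## driving-force big-M rows, one per arc
  for (e in seq_len(nE)) {
    rid <- r$id[elig[e]]
    sto <- reactionStoichiometry(net, rid)
    sto <- sto[!.isThermoExcluded(names(sto))]
    for (d in c(1, -1)) {
      const <- d * r$dg0_prime[elig[e]]
      fixedPart <- intersect(names(sto), names(fixed))
      if (length(fixedPart))
        const <- const + RT * sum(d * sto[fixedPart] * log(fixed[fixedPart]))
      freePart <- setdiff(names(sto), fixedPart)
      row <- newRow(-Inf, bigM - const)
      if (length(freePart))
        addTriplets(row, iX[match(freePart, thermoMets)],
                    RT * d * unname(sto[freePart]))
      addTriplets(row, iB, 1)
      addTriplets(row, if (d > 0) iZF[e] else iZB[e], bigM)
    }
  }
  xlb <- rep(log(bounds@default_lb), nx); xub <- rep(log(bounds@default_ub), nx)
  names(xlb) <- names(xub) <- thermoMets
  for (id in intersect(names(bounds@overrides), thermoMets)) {
    xlb[id] <- log(bounds@overrides[[id]][1])
    xub[id] <- log(bounds@overrides[[id]][2])
  }
  vlb <- c(rep(0, 2 * nE), rep(-fluxCap, nP), rep(0, 2 * nE), xlb, 1e-6)
  vub <- c(rep(fluxCap, 2 * nE), rep(fluxCap, nP), rep(1, 2 * nE), xub, 200)
  obj <- numeric(nv)
  obj[c(iZF, iZB)] <- -w
  obj[iB] <- 1 / RT
  integrality <- integer(nv); integrality[c(iZF, iZB)] <- 1L
  A <- Matrix::sparseMatrix(i = Ai, j = Aj, x = Ax, dims = c(nrow, nv))
  list(problem = lpProblem(obj, A, clb, cub, vlb, vub, integrality, "max"),
       idx = list(vf = iVF, vb = iVB, vp = iVP, zf = iZF, zb = iZB,
                  x = iX, B = iB),
       elig = elig, pseudo = pseudo, net = net)
}

.decodePathway <- function(milp, sol, query, bounds, params, tol = 1e-6) {
  net <- milp$net; r <- reactions(net)
  vf <- sol$x[milp$idx$vf]; vb <- sol$x[milp$idx$vb]
  vp <- sol$x[milp$idx$vp]
  active <- which(vf > tol | vb > tol)
  support <- data.frame(id = r$id[milp$elig][active],
                        direction = ifelse(vf[active] > tol, 1, -1))
  fluxes <- stats::setNames((vf - vb)[active], r$id[milp$elig][active])
  pfl <- stats::setNames(vp, r$id[milp$pseudo])
  fluxes <- c(fluxes, pfl[abs(pfl) > tol])
  exact <- computeMdf(net, support, bounds, params)
  S <- stoichiometry(net)
  nc <- as.numeric(S[, names(fluxes), drop = FALSE] %*% fluxes)
  names(nc) <- metaboliteIds(net)
  nc <- nc[abs(nc) > 1e-7]
  methods::new("CandidatePathway", support = support, fluxes = fluxes,
               netConversion = nc, mdf = exact@mdf,
               nReactions = nrow(support))
}

#' Enumerate thermodynamically feasible carbon-fixation pathways
#'
#' Iterates the MILP described in the package vignette: each solution is a
#' reaction support achieving the queried net conversion at steady state
#' with a strictly positive max-min driving force, found in decreasing
#' order of the joint objective B/RT - w * (number of reactions).  After
#' each solution an integer cut excludes its directed support (and all of
#' its supersets) and the model is re-solved until infeasibility,
#' `maxSolutions`, or a non-positive exact MDF.  Supports that strictly
#' contain an also-returned support are dropped so the result is the set of
#' minimal feasible supports.
#'
#' @param net a [MetabolicNetwork-class]; pruned and currency-augmented
#'   automatically when needed.
#' @param query a [pathwayQuery()].
#' @param bounds a [ConcentrationBounds-class].
#' @param params a [ThermoParams-class].
#' @param maxSolutions iteration cap.
#' @param w objective weight on the reaction count (default 1).
#' @param excludeOxygenSensitive drop oxygen-sensitive reactions first.
#' @param bigM big-M constant (kJ/mol) linking driving-force constraints to
#'   activity indicators; must exceed any attainable |dG'|.
#' @param fluxCap flux cap V per arc.
#' @param minimalOnly keep only minimal supports (default TRUE).
#' @return list of [CandidatePathway-class], in discovery (objective) order.
#' @export
enumeratePathways <- function(net, query = pathwayQuery(),
                              bounds = concentrationBounds(),
                              params = thermoParams(),
                              maxSolutions = 10, w = 1,
                              excludeOxygenSensitive = FALSE,
                              bigM = 2000, fluxCap = 1000,
                              minimalOnly = TRUE) {
  net <- .prepareForSearch(net)
  if (excludeOxygenSensitive) net <- removeOxygenSensitive(net)
  if (maxSolutions < 1) return(list())
  milp <- .buildSearchMilp(net, query, bounds, params, w, bigM, fluxCap)
  prob <- milp$problem
  found <- list()
  repeat {
    sol <- solveLp(prob, "highs")
    if (sol$status != "optimal") break
    pw <- .decodePathway(milp, sol, query, bounds, params)
    if (pw@mdf <= 1e-6) break   # guard: exact LP disagrees with big-M model
    found[[length(found) + 1L]] <- pw
    if (length(found) >= maxSolutions) break
    ## integer cut: sum of the support's indicator variables <= |support|-1
    r <- reactions(net)
    eIdx <- match(match(pw@support$id, r$id), milp$elig)
    cols <- ifelse(pw@support$direction > 0,
                   milp$idx$zf[eIdx], milp$idx$zb[eIdx])
    cut <- Matrix::sparseMatrix(i = rep(1L, length(cols)), j = cols,
                                x = rep(1, length(cols)),
                                dims = c(1L, length(prob$obj)))
    prob <- lpProblem(prob$obj, rbind(prob$A, cut),
                      c(prob$clb, -Inf), c(prob$cub, length(cols) - 1),
                      prob$vlb, prob$vub, prob$integrality, prob$sense)
  }
  if (minimalOnly && length(found) > 1) {
    keys <- lapply(found, function(p)
      paste0(p@support$id, ":", p@support$direction))
    keep <- vapply(seq_along(found), function(i) {
      !any(vapply(seq_along(found), function(j) {
        i != j && length(keys[[j]]) < length(keys[[i]]) &&
          all(keys[[j]] %in% keys[[i]])
      }, logical(1)))
    }, logical(1))
    found <- found[keep]
  }
  found
}

#' Pareto front of candidate pathways
#'
#' Returns the subset not dominated under (maximize MDF, minimize reaction
#' count); a pathway is dominated when another is at least as good in both
#' objectives and strictly better in one.  Exact ties on both coordinates
#' are all kept.
#'
#' @param pathways list of [CandidatePathway-class] (or a data.frame with
#'   columns `mdf` and `n_reactions`).
#' @return the non-dominated subset, in the input's order.
#' @export
paretoFront <- function(pathways) {
  if (is.data.frame(pathways)) {
    m <- pathways$mdf; n <- pathways$n_reactions
  } else {
    m <- vapply(pathways, function(p) p@mdf, numeric(1))
    n <- vapply(pathways, function(p) p@nReactions, numeric(1))
  }
  keep <- vapply(seq_along(m), function(i) {
    !any(m >= m[i] & n <= n[i] & (m > m[i] | n < n[i]))
  }, logical(1))
  if (is.data.frame(pathways)) pathways[keep, , drop = FALSE]
  else pathways[keep]
}

#' Net conversion of a pathway
#'
#' Recomputes S v from the pathway's fluxes (pseudo-reaction fluxes
#' included, so freely supplied currency species vanish) and returns the
#' non-zero entries; for a valid carbon-fixation pathway this is
#' `{CO2: -3, pyruvate: +1}` per mole of product.  An unbalanced
#' non-currency species that the pathway does not declare as converted is
#' an invariant violation.
#'
#' @param pathway a [CandidatePathway-class].
#' @param net the network the pathway lives in.
#' @param tol balance tolerance.
#' @return named numeric of net moles per mole product.
#' @export
netConversion <- function(pathway, net, tol = 1e-6) {
  fluxes <- pathway@fluxes
  if (!length(fluxes)) return(stats::setNames(numeric(0), character(0)))
  stopifnot(all(names(fluxes) %in% reactionIds(net)))
  S <- stoichiometry(net)
  nc <- as.numeric(S[, names(fluxes), drop = FALSE] %*% fluxes)
  names(nc) <- metaboliteIds(net)
  nc <- nc[abs(nc) > tol]
  m <- metabolites(net)
  declared <- names(pathway@netConversion)
  bad <- setdiff(names(nc)[!m$is_currency[match(names(nc), m$id)]], declared)
  bad <- setdiff(bad, declared)
  if (length(bad))
    stop("non-steady internal species: ", paste(bad, collapse = ", "),
         call. = FALSE)
  nc
}

#' ATP cost of a pathway
#'
#' Sums ATP-equivalent consumption minus production over all non-pseudo
#' reactions, weighted by flux (scaled to one mole of product).  The
#' accounting maps adenylates to phosphoanhydride-bond equivalents, default
#' ATP = 2, ADP = 1, AMP = 0, so an ATP-to-ADP conversion costs 1
#' equivalent and an ATP-to-AMP conversion (e.g. PEP synthetase) costs 2;
#' substrate-level phosphorylation is credited symmetrically.
#'
#' @param pathway a [CandidatePathway-class].
#' @param net the network the pathway lives in.
#' @param accounting named numeric of bond equivalents per adenylate base id.
#' @return ATP equivalents consumed per mole of product.
#' @export
atpCost <- function(pathway, net, accounting = c(atp = 2, adp = 1, amp = 0)) {
  fluxes <- pathway@fluxes
  if (!length(fluxes)) return(0)
  r <- reactions(net)
  fluxes <- fluxes[!r$is_pseudo[match(names(fluxes), r$id)]]
  adenylates <- c("atp", "adp", "amp", "ppi")
  cost <- 0
  for (id in names(fluxes)) {
    sto <- reactionStoichiometry(net, id)
    base <- .baseId(names(sto))
    hit <- base %in% adenylates
    if (!any(hit)) next
    unknown <- setdiff(base[hit], names(accounting))
    if (length(unknown))
      stop("cofactor(s) not in accounting table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cost <- cost - fluxes[[id]] * sum(sto[hit] * accounting[base[hit]])
  }
  unname(cost)
}

.FIXTURE_GED_SUPPORT <- data.frame(
  id = c("GND", "EDD", "EDA", "PPS", "ENO", "PGM", "PGK", "GAPD", "TPI",
         "FBA", "FBP", "TKT1", "TKT2", "TALA", "RPE", "RPI"),
  direction = c(-1, 1, 1, 1, -1, -1, -1, -1, -1, -1, 1, -1, -1, -1, -1, 1))

.FIXTURE_RUBP_SUPPORT <- data.frame(
  id = c("PRK", "RBPC", "PGK", "GAPD", "TPI", "FBA", "FBP", "TKT1", "TKT2",
         "TALA", "RPE", "RPI", "PGM", "ENO", "PYK"),
  direction = c(1, 1, -1, -1, -1, -1, 1, -1, -1, -1, -1, 1, 1, 1, 1))

#' Construct a named fixture pathway as a CandidatePathway
#'
#' Builds the GED cycle (reductive carboxylation by Gnd, Entner-Doudoroff
#' cleavage, gluconeogenesis via PEP synthetase, pentose phosphate
#' regeneration) or the RuBP (Calvin-Benson) cycle on the fixture network,
#' solves for the unique flux distribution achieving 3 CO2 -> 1 pyruvate
#' over the declared support, and certifies its MDF.
#'
#' @param which `"ged_cycle"` or `"rubp_cycle"`.
#' @param net optional preprocessed network (default: the core fixture,
#'   with the RuBP block when needed, pruned and currency-augmented).
#' @param bounds,params thermodynamic settings.
#' @param engine LP engine for the flux solve.
#' @return a [CandidatePathway-class].
#' @export
fixturePathway <- function(which = c("ged_cycle", "rubp_cycle"), net = NULL,
                           bounds = concentrationBounds(),
                           params = thermoParams(),
                           engine = c("highs", "simplex")) {
  which <- match.arg(which)
  engine <- match.arg(engine)
  if (is.null(net)) {
    net <- .prepareForSearch(buildCoreModel(includeRubp =
                                              (which == "rubp_cycle")))
  }
  support <- if (which == "ged_cycle") .FIXTURE_GED_SUPPORT
             else .FIXTURE_RUBP_SUPPORT
  pathwayFromSupport(net, support, query = pathwayQuery(),
                     bounds = bounds, params = params, engine = engine)
}

#' Build a CandidatePathway from a known directed support
#'
#' Solves the small LP for fluxes over the given support (arc fluxes
#' non-negative in the stated directions, currency pseudo-fluxes free,
#' steady state on everything except the query's net conversion) and
#' evaluates the exact MDF of the support.
#'
#' @inheritParams fixturePathway
#' @param net a preprocessed [MetabolicNetwork-class].
#' @param support data.frame with columns `id`, `direction`.
#' @param query a [pathwayQuery()].
#' @return a [CandidatePathway-class].
#' @export
pathwayFromSupport <- function(net, support, query = pathwayQuery(),
                               bounds = concentrationBounds(),
                               params = thermoParams(),
                               engine = c("highs", "simplex")) {
  engine <- match.arg(engine)
  support <- .asSupport(support)
  r <- reactions(net)
  stopifnot(all(support$id %in% r$id))
  pseudo <- which(r$is_pseudo)
  S <- stoichiometry(net)
  cols <- c(match(support$id, r$id), pseudo)
  dirs <- c(support$direction, rep(1, length(pseudo)))
  nA <- nrow(support); nP <- length(pseudo); nv <- nA + nP
  metIds <- metaboliteIds(net)
  b <- stats::setNames(rep(0, length(metIds)), metIds)
  b[query$substrate] <- -query$substrateMoles
  b[query$product] <- query$productMoles
  A <- S[, cols, drop = FALSE] %*% Matrix::Diagonal(x = dirs)
  touched <- Matrix::rowSums(abs(A)) > 0 | b != 0
  prob <- lpProblem(obj = c(rep(1, nA), rep(0, nP)),
                    A = A[touched, , drop = FALSE],
                    clb = b[touched], cub = b[touched],
                    vlb = c(rep(0, nA), rep(-1000, nP)),
                    vub = rep(1000, nv), sense = "min")
  sol <- solveLp(prob, engine)
  if (sol$status != "optimal")
    stop("no steady-state flux over the given support achieves the query",
         call. = FALSE)
  v <- sol$x * dirs
  fluxes <- stats::setNames(v, r$id[cols])
  fluxes <- fluxes[abs(fluxes) > 1e-9]
  exact <- computeMdf(net, support, bounds, params)
  nc <- as.numeric(S[, names(fluxes), drop = FALSE] %*% fluxes)
  names(nc) <- metIds
  nc <- nc[abs(nc) > 1e-7]
  methods::new("CandidatePathway", support = support, fluxes = fluxes,
               netConversion = nc, mdf = exact@mdf,
               nReactions = nrow(support))
}

#' Exhaustive subset-search oracle for pathway enumeration
#'
#' Independent brute-force reference for [enumeratePathways()] on small
#' networks: tests every reaction subset (ascending size, with superset
#' pruning) for a steady-state flux achieving the net conversion, using the
#' pure-R LP engine, keeps the minimal feasible subsets, derives their
#' (unique) flux direction pattern, and retains those with positive MDF.
#'
#' @param net a small [MetabolicNetwork-class] (<= `maxReactions` non-pseudo
#'   reactions).
#' @param query a [pathwayQuery()].
#' @param bounds,params thermodynamic settings.
#' @param maxReactions hard size cap (default 12).
#' @param engine LP engine (default the pure-R simplex, keeping the oracle
#'   independent of the MILP back end).
#' @return list of [CandidatePathway-class].
#' @export
bruteForceEnumerate <- function(net, query = pathwayQuery(),
                                bounds = concentrationBounds(),
                                params = thermoParams(),
                                maxReactions = 12,
                                engine = c("simplex", "highs")) {
  engine <- match.arg(engine)
  r <- reactions(net)
  elig <- which(!r$is_pseudo)
  if (length(elig) > maxReactions)
    stop("network too large for exhaustive enumeration (",
         length(elig), " > ", maxReactions, " reactions)", call. = FALSE)
  pseudo <- which(r$is_pseudo)
  S <- stoichiometry(net)
  metIds <- metaboliteIds(net)
  b <- stats::setNames(rep(0, length(metIds)), metIds)
  b[query$substrate] <- -query$substrateMoles
  b[query$product] <- query$productMoles
  feasible <- list()   # list of integer index vectors (into elig)
  sols <- list()
  n <- length(elig)
  for (size in seq_len(n)) {
    subsets <- utils::combn(n, size, simplify = FALSE)
    for (sub in subsets) {
      if (any(vapply(feasible, function(f) all(f %in% sub), logical(1))))
        next  # strict superset of a known feasible subset
      cols <- c(elig[sub], pseudo)
      A <- S[, cols, drop = FALSE]
      touched <- Matrix::rowSums(abs(A)) > 0 | b != 0
      if (any(b[touched] != 0 &
              Matrix::rowSums(abs(A[touched, , drop = FALSE])) == 0))
        next  # substrate/product untouched: trivially infeasible
      prob <- lpProblem(obj = rep(0, length(cols)),
                        A = A[touched, , drop = FALSE],
                        clb = b[touched], cub = b[touched],
                        vlb = rep(-1000, length(cols)),
                        vub = rep(1000, length(cols)), sense = "min")
      sol <- solveLp(prob, engine)
      if (sol$status == "optimal") {
        feasible[[length(feasible) + 1L]] <- sub
        sols[[length(feasible)]] <- sol$x
      }
    }
  }
  out <- list()
  for (k in seq_along(feasible)) {
    sub <- feasible[[k]]; x <- sols[[k]]
    v <- x[seq_along(sub)]
    support <- data.frame(id = r$id[elig[sub]],
                          direction = ifelse(v >= 0, 1, -1))
    exact <- tryCatch(computeMdf(net, support, bounds, params,
                                 engine = engine),
                      error = function(e) NULL)
    if (is.null(exact) || exact@mdf <= 1e-6) next
    fluxes <- stats::setNames(c(v, x[-seq_along(sub)]), r$id[c(elig[sub], pseudo)])
    fluxes <- fluxes[abs(fluxes) > 1e-9]
    nc <- as.numeric(S[, names(fluxes), drop = FALSE] %*% fluxes)
    names(nc) <- metIds
    nc <- nc[abs(nc) > 1e-7]
    out[[length(out) + 1L]] <- methods::new(
      "CandidatePathway", support = support, fluxes = fluxes,
      netConversion = nc, mdf = exact@mdf, nReactions = nrow(support))
  }
  out
}
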