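## Readers and writers: BiGG-style JSON models and the tabular fixture format.

#' Default currency metabolite base identifiers
#'
#' Ubiquitous cofactor/inorganic species that are supplied or regenerated
#' freely during pathway search: ATP/ADP/AMP/phosphate, the NAD(P) pairs,
#' protons, water, oxygen, ammonia and CO2.  CO2 is flagged as currency for
#' free supply but remains the counted substrate of the search query.
#' @export
currencyBaseIds <- function() {
  c("atp", "adp", "amp", "pi", "ppi", "nad", "nadh", "nadp", "nadph",
    "h", "h2o", "o2", "nh4", "co2")
}

.baseId <- function(id) sub("_[a-z][a-z0-9]?$", "", id)
.compartmentOf <- function(id) {
  m <- regmatches(id, regexpr("_[a-z][a-z0-9]?$", id))
  ifelse(lengths(regmatches(id, gregexpr("_[a-z][a-z0-9]?$", id))) > 0,
         sub("^_", "", m), "")
}

.carbonsFromFormula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NA_integer_)
  m <- regmatches(formula, regexpr("C[0-9]*(?![a-z])", formula, perl = TRUE))
  if (!length(m)) return(0L)
  n <- sub("^C", "", m)
  if (!nzchar(n)) 1L else as.integer(n)
}

#' Read a BiGG-style JSON metabolic model
#'
#' Parses the standard BiGG JSON dialect (`metabolites`, `reactions`,
#' `lower_bound`/`upper_bound`).  Exchange reactions are detected by the
#' `EX_` prefix; transport reactions by participation of the same base
#' metabolite id in two or more compartments.  Carbon counts are taken from
#' chemical formulas when present.
#'
#' @param path path to a JSON file.
#' @param currency character vector of currency base ids
#'   (default [currencyBaseIds()]).
#' @return a [MetabolicNetwork-class].
#' @export
readBiggJson <- function(path, currency = currencyBaseIds()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  model <- tryCatch(jsonlite::read_json(path),
                    error = function(e) stop("malformed JSON in '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
  for (key in c("metabolites", "reactions")) {
    if (is.null(model[[key]]))
      stop("malformed BiGG JSON: missing key '", key, "'", call. = FALSE)
  }
  mets <- do.call(rbind, lapply(model$metabolites, function(m) {
    if (is.null(m$id)) stop("malformed BiGG JSON: metabolite without 'id'",
                            call. = FALSE)
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               carbons = .carbonsFromFormula(m$formula),
               compartment = if (is.null(m$compartment))
                 .compartmentOf(m$id) else m$compartment,
               is_currency = .baseId(m$id) %in% currency,
               fixed_conc = NA_real_, stringsAsFactors = FALSE)
  }))
  if (is.null(mets)) mets <- .emptyMetTable()
  sto <- list(); rxnRows <- list()
  for (rx in model$reactions) {
    if (is.null(rx$id)) stop("malformed BiGG JSON: reaction without 'id'",
                             call. = FALSE)
    coef <- vapply(rx$metabolites, as.numeric, numeric(1))
    comps <- .compartmentOf(names(coef))
    bases <- .baseId(names(coef))
    isTransport <- any(duplicated(bases)) &&
      any(vapply(split(comps, bases), function(x) length(unique(x)) > 1,
                 logical(1)))
    sto[[rx$id]] <- coef
    rxnRows[[rx$id]] <- data.frame(
      id = rx$id, dg0_prime = NA_real_,
      lower_bound = if (is.null(rx$lower_bound)) -1000 else rx$lower_bound,
      upper_bound = if (is.null(rx$upper_bound)) 1000 else rx$upper_bound,
      oxygen_sensitive = FALSE,
      is_exchange = grepl("^EX_", rx$id),
      is_transport = isTransport, is_pseudo = FALSE,
      notes = "", stringsAsFactors = FALSE)
  }
  rxns <- if (length(rxnRows)) do.call(rbind, rxnRows) else .emptyRxnTable()
  MetabolicNetwork(mets, rxns, sto,
                   provenance = paste("BiGG JSON:", basename(path)))
}

## Parse one equation string like "6pgc_c + nadp_c <-> ru5p__D_c + co2_c".
## Returns list(stoich = named numeric, reversible = logical).
.parseEquation <- function(eq) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->"
           else if (grepl("->", eq, fixed = TRUE)) "->"
           else stop("unparseable equation (no arrow): '", eq, "'",
                     call. = FALSE)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  if (length(sides) != 2)
    stop("unparseable equation: '", eq, "'", call. = FALSE)
  parseSide <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric()
    for (tm in terms) {
      if (!nzchar(tm)) stop("unparseable equation: '", eq, "'", call. = FALSE)
      parts <- strsplit(tm, "[ ]+")[[1]]
      if (length(parts) == 1) {
        coef <- 1; met <- parts[1]
      } else if (length(parts) == 2 &&
                 grepl("^[0-9.]+$", parts[1])) {
        coef <- as.numeric(parts[1]); met <- parts[2]
      } else {
        stop("unparseable term '", tm, "' in equation: '", eq, "'",
             call. = FALSE)
      }
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], +1)
  sto <- c(lhs, numeric())
  for (m in names(rhs)) sto[m] <- (if (is.na(sto[m])) 0 else sto[m]) + rhs[m]
  sto <- sto[sto != 0]
  if (!length(sto))
    stop("degenerate reaction with zero net stoichiometry: '", eq, "'",
         call. = FALSE)
  list(stoich = sto, reversible = arrow == "<->")
}

.formatEquation <- function(sto, reversible) {
  fmt <- function(v) paste(vapply(names(v), function(m) {
    if (abs(v[[m]] - 1) < 1e-12) m else paste(format(v[[m]]), m)
  }, character(1)), collapse = " + ")
  lhs <- -sto[sto < 0]; rhs <- sto[sto > 0]
  paste(fmt(lhs), if (reversible) "<->" else "->", fmt(rhs))
}

#' Read a network from the tabular fixture format
#'
#' Expects `metabolites.tsv` (columns id, name, carbons, compartment,
#' currency, optionally fixed_conc) and `reactions.tsv` (columns id,
#' equation, dg0_prime_kj_mol, oxygen_sensitive, notes, optionally
#' lower_bound/upper_bound) in one directory, tab-separated, UTF-8, with
#' `#` comment lines.  Equations use `a A + b B -> c C` with `->` or `<->`;
#' directionality is stored only as flux bounds.
#'
#' @param dir directory holding the two files.
#' @return a [MetabolicNetwork-class].
#' @export
readNetworkTable <- function(dir) {
  mPath <- file.path(dir, "metabolites.tsv")
  rPath <- file.path(dir, "reactions.tsv")
  for (p in c(mPath, rPath)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  readTsv <- function(p) {
    utils::read.delim(p, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = NA,
                      fileEncoding = "UTF-8")
  }
  mt <- readTsv(mPath)
  rt <- readTsv(rPath)
  if (nrow(mt) == 0 && nrow(rt) == 0) {
    return(MetabolicNetwork(provenance = paste("fixture tables:", dir)))
  }
  mets <- data.frame(id = as.character(mt$id),
                     name = if (is.null(mt$name)) mt$id else mt$name,
                     carbons = as.integer(mt$carbons),
                     compartment = if (is.null(mt$compartment))
                       .compartmentOf(mt$id) else mt$compartment,
                     is_currency = as.logical(mt$currency),
                     fixed_conc = if (is.null(mt$fixed_conc)) NA_real_
                       else as.numeric(mt$fixed_conc),
                     stringsAsFactors = FALSE)
  sto <- list(); rows <- list()
  for (k in seq_len(nrow(rt))) {
    id <- as.character(rt$id[k])
    parsed <- tryCatch(.parseEquation(rt$equation[k]), error = function(e) {
      stop("line ", k, " of reactions.tsv (reaction '", id, "'): ",
           conditionMessage(e), call. = FALSE)
    })
    unknown <- setdiff(names(parsed$stoich), mets$id)
    if (length(unknown))
      stop("reaction '", id, "' uses unknown metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    sto[[id]] <- parsed$stoich
    rows[[id]] <- data.frame(
      id = id,
      dg0_prime = suppressWarnings(as.numeric(rt$dg0_prime_kj_mol[k])),
      lower_bound = if (!is.null(rt$lower_bound)) as.numeric(rt$lower_bound[k])
        else if (parsed$reversible) -1000 else 0,
      upper_bound = if (!is.null(rt$upper_bound)) as.numeric(rt$upper_bound[k])
        else 1000,
      oxygen_sensitive = as.logical(rt$oxygen_sensitive[k]),
      is_exchange = grepl("^EX_", id),
      is_transport = FALSE,  # recomputed below
      is_pseudo = FALSE,
      notes = if (is.null(rt$notes)) "" else as.character(rt$notes[k]),
      stringsAsFactors = FALSE)
  }
  rxns <- do.call(rbind, rows)
  for (k in seq_len(nrow(rxns))) {
    ids <- names(sto[[rxns$id[k]]])
    bases <- .baseId(ids); comps <- .compartmentOf(ids)
    rxns$is_transport[k] <- any(vapply(split(comps, bases),
                                       function(x) length(unique(x)) > 1,
                                       logical(1)))
  }
  MetabolicNetwork(mets, rxns, sto,
                   provenance = paste("fixture tables:", dir))
}

#' Write a network in the tabular fixture format
#'
#' Inverse of [readNetworkTable()]: writes `metabolites.tsv` and
#' `reactions.tsv` (with explicit bound columns so arbitrary bounds
#' round-trip).  Pseudo-reactions are not serialized; re-add them with
#' [addCurrencyExchanges()].
#'
#' @param net a [MetabolicNetwork-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeNetworkTable <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- metabolites(net)
  mOut <- data.frame(id = m$id, name = m$name, carbons = m$carbons,
                     compartment = m$compartment, currency = m$is_currency,
                     fixed_conc = m$fixed_conc)
  r <- reactions(net)
  keep <- !r$is_pseudo
  r <- r[keep, , drop = FALSE]
  eqs <- vapply(r$id, function(id) {
    sto <- reactionStoichiometry(net, id)
    .formatEquation(sto, reversible = r$lower_bound[r$id == id] < 0)
  }, character(1))
  rOut <- data.frame(id = r$id, equation = eqs,
                     dg0_prime_kj_mol = r$dg0_prime,
                     oxygen_sensitive = r$oxygen_sensitive,
                     lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                     notes = r$notes)
  hdr <- function(path, what) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    writeLines(paste0("# latentpath ", what, " table; ",
                      net@provenance), con)
    con
  }
  con <- hdr(file.path(dir, "metabolites.tsv"), "metabolite")
  utils::write.table(mOut, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  con <- hdr(file.path(dir, "reactions.tsv"), "reaction")
  utils::write.table(rOut, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(dir)
}
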