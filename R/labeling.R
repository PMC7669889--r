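## Positional 13C atom-transition simulation of the GED shunt and mapping
## onto proteinogenic amino-acid isotopologue distributions.
##
## Atom routing (carbons numbered 1-based from the carboxyl/aldehyde end):
##   pentose (ribose/xylose) C1..C5      -> Ru5P C1..C5
##   Gnd carboxylation: CO2 -> 6PG C1;      Ru5P C1..C5 -> 6PG C2..C6
##   ED cleavage (Edd+Eda): 6PG C1..C3   -> pyruvate (Eda) C1..C3
##                          6PG C4..C6   -> GAP C1..C3
##   lower glycolysis: GAP C1..C3        -> 3PG/pyruvate C1..C3
## Amino acids: SER <- 3PG; GLY <- SER C1-C2; ALA <- pyruvate pool;
## VAL <- pyruvate A (all three carbons) + pyruvate B C2-C3 (B's carboxyl
## is lost as CO2); HIS <- five R5P carbons + serine's beta-carbon (C3).
## All fractions are exact dyadic rationals, so equality tests are exact.

#' Atom-transition table of the labeling model
#'
#' @return data.frame with columns `pool`, `carbon`, `source_pool`,
#'   `source_carbon` describing every positional carbon transition used by
#'   the simulator.
#' @export
atomMapTable <- function() {
  rows <- list()
  add <- function(pool, carbon, src, srcC)
    rows[[length(rows) + 1L]] <<- data.frame(pool = pool, carbon = carbon,
                                             source_pool = src,
                                             source_carbon = srcC)
  for (i in 1:5) add("ru5p", i, "pentose", i)
  add("6pg", 1, "co2", 1)
  for (i in 1:5) add("6pg", i + 1, "ru5p", i)
  for (i in 1:3) add("eda_pyruvate", i, "6pg", i)
  for (i in 1:3) add("gap", i, "6pg", i + 3)
  for (i in 1:3) add("gap_pyruvate", i, "gap", i)
  for (i in 1:3) add("serine", i, "gap", i)
  for (i in 1:2) add("glycine", i, "serine", i)
  for (i in 1:3) add("alanine", i, "pyruvate_pool", i)
  for (i in 1:3) add("valine", i, "pyruvate_A", i)
  for (i in 2:3) add("valine", i + 2, "pyruvate_B", i)
  for (i in 1:5) add("histidine", i, "r5p", i)
  add("histidine", 6, "serine", 3)
  do.call(rbind, rows)
}

#' Define a tracer feeding regime
#'
#' @param substrate `"ribose"` or `"xylose"` (both reach Ru5P with their
#'   carbon skeleton intact, so positions map 1:1).
#' @param labeledPositions integer carbon positions of the substrate that
#'   carry 13C (e.g. `1` for 1-13C-xylose).
#' @param co2Labeled logical, 13CO2 in the headspace.
#' @return a named list.
#' @export
tracerSpec <- function(substrate = c("ribose", "xylose"),
                       labeledPositions = integer(0), co2Labeled = FALSE) {
  substrate <- match.arg(substrate)
  labeledPositions <- as.integer(labeledPositions)
  if (length(labeledPositions) &&
      (any(labeledPositions < 1) || any(labeledPositions > 5)))
    stop("labeled positions must lie in 1..5", call. = FALSE)
  list(substrate = substrate, labeledPositions = labeledPositions,
       co2Labeled = isTRUE(co2Labeled))
}

#' Propagate positional labels through the GED shunt
#'
#' @param tracer a [tracerSpec()].
#' @return list of logical label patterns for `ru5p` (5 carbons), `pg6`
#'   (6-phosphogluconate, 6 carbons), `eda_pyruvate` and `gap` (3 carbons
#'   each), indexed from the carboxyl/aldehyde end.
#' @export
#' @examples
#' propagateLabels(tracerSpec("ribose", co2Labeled = TRUE))$gap  # unlabeled
propagateLabels <- function(tracer) {
  pentose <- seq_len(5) %in% tracer$labeledPositions
  pg6 <- c(tracer$co2Labeled, pentose)
  list(ru5p = pentose, pg6 = pg6,
       eda_pyruvate = pg6[1:3], gap = pg6[4:6])
}

.mplus <- function(n) paste0("M+", 0:n)

## point distribution with k labels over n carbons
.pointDist <- function(k, n) {
  f <- numeric(n + 1); f[k + 1] <- 1
  stats::setNames(f, .mplus(n))
}

#' Isotopologue distribution of the mixed pyruvate pool
#'
#' Pyruvate is produced both directly by Eda and from GAP via lower
#' glycolysis; one of each per shunt turn, so the pool defaults to an
#' equimolar two-component mixture.
#'
#' @param edaPattern,gapPattern logical 3-vectors (from
#'   [propagateLabels()]).
#' @param mix fraction of the pool coming from Eda (default 0.5).
#' @return named numeric `M+0 ... M+3`, summing to 1.
#' @export
pyruvatePoolMixture <- function(edaPattern, gapPattern, mix = 0.5) {
  stopifnot(length(edaPattern) == 3, length(gapPattern) == 3,
            mix >= 0, mix <= 1)
  f <- numeric(4)
  f[sum(edaPattern) + 1] <- f[sum(edaPattern) + 1] + mix
  f[sum(gapPattern) + 1] <- f[sum(gapPattern) + 1] + (1 - mix)
  stats::setNames(f, .mplus(3))
}

#' Predicted amino-acid isotopologue distributions under the GED shunt
#'
#' Serine and glycine inherit GAP (via 3PG) and are point distributions;
#' alanine samples the pyruvate pool; valine condenses two independent
#' draws from the pool, losing the acceptor's carboxyl carbon as CO2;
#' histidine combines the five R5P carbons with serine's beta-carbon.
#'
#' @param tracer a [tracerSpec()].
#' @param mix Eda fraction of the pyruvate pool (default 0.5).
#' @return named list of isotopologue fraction vectors (`M+0 ...`) for
#'   `SER`, `GLY`, `ALA`, `VAL`, `HIS`.
#' @export
#' @examples
#' # unlabeled ribose + 13CO2: half of alanine and valine labeled
#' aminoAcidIsotopologues(tracerSpec("ribose", co2Labeled = TRUE))$ALA
aminoAcidIsotopologues <- function(tracer, mix = 0.5) {
  pat <- propagateLabels(tracer)
  pool <- list(list(p = mix, k = sum(pat$eda_pyruvate),
                    pattern = pat$eda_pyruvate),
               list(p = 1 - mix, k = sum(pat$gap), pattern = pat$gap))
  ala <- pyruvatePoolMixture(pat$eda_pyruvate, pat$gap, mix)
  val <- stats::setNames(numeric(6), .mplus(5))
  for (a in pool) for (b in pool) {
    k <- a$k + sum(b$pattern[2:3])   # B's C1 (carboxyl) lost as CO2
    val[k + 1] <- val[k + 1] + a$p * b$p
  }
  list(SER = .pointDist(sum(pat$gap), 3),
       GLY = .pointDist(sum(pat$gap[1:2]), 2),
       ALA = ala,
       VAL = val,
       HIS = .pointDist(sum(pat$ru5p) + pat$gap[3], 6))
}

#' L1 distance between isotopologue distributions
#'
#' Pads the shorter vector with zeros and returns the sum of absolute
#' deviations.  Given two named lists (per-species distributions), returns
#' the per-species distances with a `total` attribute; the species sets
#' must match.
#'
#' @param predicted,observed numeric fraction vectors, or named lists of
#'   them.
#' @return numeric distance (or named vector with attribute `total`).
#' @export
compareDistributions <- function(predicted, observed) {
  if (is.list(predicted) || is.list(observed)) {
    if (!setequal(names(predicted), names(observed)))
      stop("species sets differ: ",
           paste(symdiff <- union(setdiff(names(predicted), names(observed)),
                                  setdiff(names(observed), names(predicted))),
                 collapse = ", "), call. = FALSE)
    d <- vapply(names(predicted), function(s)
      compareDistributions(predicted[[s]], observed[[s]]), numeric(1))
    attr(d, "total") <- sum(d)
    return(d)
  }
  if (anyNA(predicted) || anyNA(observed))
    stop("distributions must not contain NA", call. = FALSE)
  n <- max(length(predicted), length(observed))
  pad <- function(v) c(v, numeric(n - length(v)))
  sum(abs(pad(unname(predicted)) - pad(unname(observed))))
}
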