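# Positional 13C label propagation and amino-acid isotopologues.
# All expected fractions are dyadic rationals, so comparisons are exact.

test_that("the atom map conserves carbon and gives each carbon one source", {
  am <- atomMapTable()
  expect_equal(anyDuplicated(am[, c("pool", "carbon")]), 0L)
  counts <- table(am$pool)
  expect_equal(unname(counts[["6pg"]]), 6)      # CO2 + 5 Ru5P carbons
  expect_equal(unname(counts[["eda_pyruvate"]]), 3)
  expect_equal(unname(counts[["gap"]]), 3)
  expect_equal(unname(counts[["valine"]]), 5)   # 3 + 2 (one carboxyl lost)
  expect_equal(unname(counts[["histidine"]]), 6)
})

test_that("13CO2 enters as the carboxyl of 6PG and GAP stays unlabeled", {
  pat <- propagateLabels(tracerSpec("ribose", co2Labeled = TRUE))
  expect_equal(pat$pg6, c(TRUE, rep(FALSE, 5)))
  expect_equal(pat$eda_pyruvate, c(TRUE, FALSE, FALSE))
  expect_equal(pat$gap, c(FALSE, FALSE, FALSE))
})

test_that("no tracer means no label anywhere", {
  pat <- propagateLabels(tracerSpec("ribose"))
  expect_false(any(unlist(pat)))
  iso <- aminoAcidIsotopologues(tracerSpec("xylose"))
  for (sp in names(iso)) expect_identical(unname(iso[[sp]][1]), 1)
})

test_that("1-13C-xylose plus 13CO2 doubly labels the Eda pyruvate", {
  pat <- propagateLabels(tracerSpec("xylose", 1, co2Labeled = TRUE))
  expect_equal(pat$eda_pyruvate, c(TRUE, TRUE, FALSE))
  expect_equal(pat$gap, c(FALSE, FALSE, FALSE))
})

test_that("the pyruvate pool mixes Eda and GAP pyruvate", {
  pat <- propagateLabels(tracerSpec("ribose", co2Labeled = TRUE))
  mixed <- pyruvatePoolMixture(pat$eda_pyruvate, pat$gap)
  expect_identical(unname(mixed), c(0.5, 0.5, 0, 0))
  pure <- pyruvatePoolMixture(pat$eda_pyruvate, pat$gap, mix = 1)
  expect_identical(unname(pure), c(0, 1, 0, 0))
  pat2 <- propagateLabels(tracerSpec("xylose", 1, co2Labeled = TRUE))
  mixed2 <- pyruvatePoolMixture(pat2$eda_pyruvate, pat2$gap)
  expect_identical(unname(mixed2), c(0.5, 0, 0.5, 0))
})

test_that("amino-acid predictions reproduce the printed patterns exactly", {
  # unlabeled pentose + 13CO2: SER/GLY unlabeled, half of ALA and VAL M+1
  a <- aminoAcidIsotopologues(tracerSpec("ribose", co2Labeled = TRUE))
  expect_identical(unname(a$SER), c(1, 0, 0, 0))
  expect_identical(unname(a$GLY), c(1, 0, 0))
  expect_identical(unname(a$ALA), c(0.5, 0.5, 0, 0))
  expect_identical(unname(a$VAL), c(0.5, 0.5, 0, 0, 0, 0))
  # 1-13C-xylose + 13CO2: ALA half M+0 / half M+2, VAL 1:1:1:1, HIS M+1
  b <- aminoAcidIsotopologues(tracerSpec("xylose", 1, co2Labeled = TRUE))
  expect_identical(unname(b$ALA), c(0.5, 0, 0.5, 0))
  expect_identical(unname(b$VAL), c(0.25, 0.25, 0.25, 0.25, 0, 0))
  expect_identical(unname(b$HIS), c(0, 1, 0, 0, 0, 0, 0))
  expect_identical(unname(b$SER), c(1, 0, 0, 0))
  expect_identical(unname(b$GLY), c(1, 0, 0))
})

allTracers <- c(
  lapply(0:5, function(p) tracerSpec("xylose",
                                     if (p > 0) p else integer(),
                                     co2Labeled = TRUE)),
  lapply(0:5, function(p) tracerSpec("ribose",
                                     if (p > 0) p else integer(),
                                     co2Labeled = FALSE)),
  list(tracerSpec("xylose", c(1, 5), co2Labeled = TRUE)))

test_that("distributions are simplex vectors for every tracer", {
  for (tr in allTracers) {
    iso <- aminoAcidIsotopologues(tr)
    for (sp in names(iso)) {
      expect_equal(sum(iso[[sp]]), 1, tolerance = 1e-12)
      expect_true(all(iso[[sp]] >= 0 & iso[[sp]] <= 1))
    }
  }
})

test_that("expected labels are conserved through valine condensation", {
  for (tr in allTracers) {
    pat <- propagateLabels(tr)
    iso <- aminoAcidIsotopologues(tr)
    meanLabels <- function(f) sum((seq_along(f) - 1) * f)
    ePool <- meanLabels(iso$ALA)
    # E[VAL] = E[pyr A] + E[pyr B] - E[B's carboxyl label]
    eB1 <- 0.5 * pat$eda_pyruvate[1] + 0.5 * pat$gap[1]
    expect_equal(meanLabels(iso$VAL), 2 * ePool - eB1, tolerance = 1e-12)
  }
})

test_that("a Monte-Carlo molecule simulation reproduces the distributions", {
  # independent stochastic oracle: draw individual molecules
  set.seed(7)
  n <- 40000
  for (tr in list(tracerSpec("ribose", co2Labeled = TRUE),
                  tracerSpec("xylose", 1, co2Labeled = TRUE))) {
    pat <- propagateLabels(tr)
    iso <- aminoAcidIsotopologues(tr)
    drawPyr <- function(k) {
      eda <- runif(k) < 0.5
      ifelse(eda, sum(pat$eda_pyruvate), sum(pat$gap))
    }
    alaCounts <- tabulate(drawPyr(n) + 1, nbins = 4)
    expect_lt(sum(abs(alaCounts / n - iso$ALA)), 0.02)
    aFull <- drawPyr(n)
    bTail <- {
      eda <- runif(n) < 0.5
      ifelse(eda, sum(pat$eda_pyruvate[2:3]), sum(pat$gap[2:3]))
    }
    valCounts <- tabulate(aFull + bTail + 1, nbins = 6)
    expect_lt(sum(abs(valCounts / n - iso$VAL)), 0.02)
  }
})

test_that("losing a non-carboxyl carbon instead would break the 1:1:1:1 pattern", {
  # if the condensation retained B's C1-C2 (losing C3) the valine pattern
  # under 1-13C-xylose + 13CO2 would collapse to 1:0:2:0:1
  pat <- propagateLabels(tracerSpec("xylose", 1, co2Labeled = TRUE))
  pool <- list(list(p = 0.5, pat = pat$eda_pyruvate),
               list(p = 0.5, pat = pat$gap))
  alt <- numeric(6)
  for (a in pool) for (b in pool) {
    k <- sum(a$pat) + sum(b$pat[1:2])
    alt[k + 1] <- alt[k + 1] + a$p * b$p
  }
  expect_identical(alt, c(0.25, 0, 0.5, 0, 0.25, 0))
  real <- aminoAcidIsotopologues(tracerSpec("xylose", 1,
                                            co2Labeled = TRUE))$VAL
  expect_gt(compareDistributions(alt, real), 0.5)
})

test_that("L1 comparison pads, errors on NA, and matches hand arithmetic", {
  expect_equal(compareDistributions(c(1, 0), c(1, 0)), 0)
  expect_equal(compareDistributions(c(1, 0), c(0, 1)), 2)
  expect_equal(compareDistributions(c(0.25, 0.25, 0.25, 0.25),
                                    c(0.3, 0.2, 0.25, 0.25)), 0.1)
  expect_equal(compareDistributions(c(1), c(0.5, 0.5)), 1)
  expect_error(compareDistributions(c(1, NA), c(1, 0)), "NA")
  got <- compareDistributions(list(A = c(1, 0), B = c(0, 1)),
                              list(A = c(1, 0), B = c(1, 0)))
  expect_equal(unname(got["B"]), 2)
  expect_equal(attr(got, "total"), 2)
  expect_error(compareDistributions(list(A = c(1)), list(B = c(1))),
               "species")
})

test_that("tracer validation rejects out-of-range positions", {
  expect_error(tracerSpec("xylose", 6), "1..5")
  expect_error(tracerSpec("glucose"), "arg")
})
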