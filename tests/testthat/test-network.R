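# Network data model, readers/writers and preprocessing.

test_that("minimal hand-written BiGG JSON round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  writeMinimalBigg(path)
  net <- readBiggJson(path)
  expect_equal(nrow(metabolites(net)), 3)
  expect_equal(nrow(reactions(net)), 2)
  expect_equal(metabolites(net)$carbons, c(3L, 3L, 3L))
  expect_true(reactions(net)$is_transport[reactions(net)$id == "Bt"])
  expect_false(reactions(net)$is_transport[reactions(net)$id == "R1"])
})

test_that("BiGG reader rejects malformed input", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(readBiggJson(bad), "malformed")
  noKey <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(metabolites = list()), noKey, auto_unbox = TRUE)
  expect_error(readBiggJson(noKey), "reactions")
  undeclared <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "a_c")),
    reactions = list(list(id = "R1",
                          metabolites = list(a_c = -1, ghost_c = 1)))),
    undeclared, auto_unbox = TRUE)
  expect_error(readBiggJson(undeclared), "ghost_c")
})

test_that("fixture model exposes the expected reaction ids", {
  ids <- reactionIds(coreNet)
  expect_true(all(c("GND", "EDD", "EDA", "PFK", "ZWF") %in% ids))
})

test_that("equation parsing handles coefficients, arrows and errors", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tname\tcarbons\tcompartment\tcurrency",
               "6pgc_c\t6PG\t6\tc\tFALSE",
               "nadp_c\tNADP\t21\tc\tTRUE",
               "ru5p__D_c\tRu5P\t5\tc\tFALSE",
               "co2_c\tCO2\t1\tc\tTRUE",
               "nadph_c\tNADPH\t21\tc\tTRUE"),
             file.path(dir, "metabolites.tsv"))
  writeLines(c("id\tequation\tdg0_prime_kj_mol\toxygen_sensitive\tnotes",
               paste0("GND\t6pgc_c + nadp_c <-> ru5p__D_c + co2_c + nadph_c",
                      "\t-1.5\tFALSE\t")),
             file.path(dir, "reactions.tsv"))
  net <- readNetworkTable(dir)
  sto <- reactionStoichiometry(net, "GND")
  expect_length(sto, 5)
  expect_equal(reactions(net)$dg0_prime, -1.5)
  expect_equal(reactions(net)$lower_bound, -1000)  # "<->" stored as bounds

  # degenerate zero-net equation
  writeLines(c("id\tequation\tdg0_prime_kj_mol\toxygen_sensitive\tnotes",
               "BAD\tco2_c -> co2_c\tNA\tFALSE\t"),
             file.path(dir, "reactions.tsv"))
  expect_error(readNetworkTable(dir), "zero net stoichiometry")

  # unknown metabolite is named
  writeLines(c("id\tequation\tdg0_prime_kj_mol\toxygen_sensitive\tnotes",
               "BAD\tco2_c -> mystery_c\tNA\tFALSE\t"),
             file.path(dir, "reactions.tsv"))
  expect_error(readNetworkTable(dir), "mystery_c")
})

test_that("empty tables give an empty network", {
  dir <- withr::local_tempdir()
  writeLines("id\tname\tcarbons\tcompartment\tcurrency",
             file.path(dir, "metabolites.tsv"))
  writeLines("id\tequation\tdg0_prime_kj_mol\toxygen_sensitive\tnotes",
             file.path(dir, "reactions.tsv"))
  net <- readNetworkTable(dir)
  expect_equal(nrow(metabolites(net)), 0)
  expect_equal(nrow(reactions(net)), 0)
})

test_that("write/read round-trip reproduces the fixture field by field", {
  dir <- withr::local_tempdir()
  writeNetworkTable(coreNet, dir)
  back <- readNetworkTable(dir)
  expect_equal(metabolites(back), metabolites(coreNet))
  r1 <- reactions(coreNet); r2 <- reactions(back)
  expect_equal(r2[names(r2) != "notes"], r1[names(r1) != "notes"])
  expect_equal(as.matrix(stoichiometry(back)),
               as.matrix(stoichiometry(coreNet)))
})

test_that("duplicate ids are rejected by validity", {
  expect_error(MetabolicNetwork(
    metabolites = data.frame(id = c("a_c", "a_c")),
    reactions = data.frame(id = "R1"),
    stoichiometry = list(R1 = c(a_c = 1))), "duplicate")
})

test_that("pruning removes exchange/transport/non-cytosolic and is idempotent", {
  pruned <- pruneForSearch(coreNet)
  r <- reactions(pruned)
  expect_false(any(r$is_exchange | r$is_transport))
  S <- stoichiometry(pruned)
  foreign <- metabolites(pruned)$compartment != "c"
  expect_true(all(Matrix::rowSums(abs(S[foreign, , drop = FALSE])) == 0))
  expect_equal(reactions(pruneForSearch(pruned)), r)
  # counts: flag scan of the authored fixture
  r0 <- reactions(coreNet)
  expect_equal(nrow(r), nrow(r0) - sum(r0$is_exchange | r0$is_transport))
})

test_that("currency augmentation adds 7 flagged pseudo-reactions", {
  aug <- addCurrencyExchanges(pruneForSearch(coreNet))
  r <- reactions(aug)
  expect_equal(sum(r$is_pseudo), 7)
  expect_true(all(grepl("^PSEUDO_", r$id[r$is_pseudo])))
  # empty spec leaves the network unchanged
  expect_identical(addCurrencyExchanges(coreNet, list()), coreNet)
  # missing species are listed
  tiny <- toyNoRoute()
  expect_error(
    addCurrencyExchanges(tiny, list(regeneration = list(), free = "h_c")),
    "h_c")
})

test_that("prune and currency augmentation commute on the fixture", {
  a <- addCurrencyExchanges(pruneForSearch(coreNet))
  b <- pruneForSearch(addCurrencyExchanges(
    coreNet, defaultCurrencySpec(coreNet)))
  expect_setequal(reactionIds(a), reactionIds(b))
})

test_that("carbon balance holds on the fixture and violations are caught", {
  expect_identical(carbonBalanceCheck(coreNet), character())
  expect_identical(carbonBalanceCheck(coreNetRubp), character())
  expect_identical(carbonBalanceCheck(buildCoreModel(includeTca = TRUE)),
                   character())
  # decarboxylation missing its CO2 is flagged
  mets <- metabolites(coreNet)
  bad <- MetabolicNetwork(mets, data.frame(id = "BADPDH"),
                          list(BADPDH = c(pyr_c = -1, coa_c = -1,
                                          accoa_c = 1)))
  expect_identical(carbonBalanceCheck(bad), "BADPDH")
  # unknown carbon counts are named
  m2 <- mets; m2$carbons[m2$id == "pyr_c"] <- NA
  bad2 <- MetabolicNetwork(m2, data.frame(id = "BADPDH"),
                           list(BADPDH = c(pyr_c = -1, coa_c = -1,
                                           accoa_c = 1)))
  expect_error(carbonBalanceCheck(bad2), "pyr_c")
  # exchange-only network passes trivially
  exOnly <- MetabolicNetwork(data.frame(id = "co2_e", carbons = 1L),
                             data.frame(id = "EX_co2_e"),
                             list(EX_co2_e = c(co2_e = -1)))
  expect_identical(carbonBalanceCheck(exOnly), character())
})

test_that("column carbon sums of S vanish for all internal reactions", {
  m <- metabolites(coreNet)
  carb <- ifelse(is.na(m$carbons), 0, m$carbons)
  r <- reactions(coreNet)
  sums <- as.numeric(carb %*% stoichiometry(coreNet))
  expect_true(all(abs(sums[!r$is_exchange]) < 1e-12))
})

test_that("oxygen-sensitive removal drops PFL and nothing else", {
  out <- removeOxygenSensitive(coreNet)
  expect_setequal(setdiff(reactionIds(coreNet), reactionIds(out)), "PFL")
  none <- removeOxygenSensitive(out)
  expect_equal(reactions(none), reactions(out))
})
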