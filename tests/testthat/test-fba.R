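# Model curations, pathway variants, and FBA yield predictions.

curatedNet <- suppressWarnings(applyCurations(coreNet))

test_that("curations modify a model that carries the named reactions", {
  mets <- data.frame(
    id = c("h_p", "h_c", "nadh_c", "nad_c", "nadp_c", "nadph_c",
           "hom__L_c", "aspsa_c", "fe2_e", "thr__L_c", "gly_c", "acald_c"),
    carbons = c(0L, 0L, 21L, 21L, 21L, 21L, 4L, 4L, 0L, 4L, 2L, 2L),
    compartment = c("p", rep("c", 7), "e", "c", "c", "c"))
  sto <- list(
    THD2pp = c(h_p = -2, nadh_c = -1, nadp_c = -1,
               h_c = 2, nad_c = 1, nadph_c = 1),
    HSDy = c(hom__L_c = -1, nadp_c = -1, aspsa_c = 1, nadph_c = 1),
    GLYCK = c(acald_c = -1, gly_c = 1),
    EX_fe2_e = c(fe2_e = -1),
    THRA = c(thr__L_c = -1, gly_c = 1, acald_c = 1))
  rxns <- data.frame(id = names(sto))
  gsm <- MetabolicNetwork(mets, rxns, sto)
  cur <- suppressWarnings(applyCurations(gsm))
  # (i) one translocated proton
  expect_equal(unname(reactionStoichiometry(cur, "THD2pp")["h_p"]), -1)
  # (ii) irreversible toward homoserine
  r <- reactions(cur)
  expect_equal(r$upper_bound[r$id == "HSDy"], 0)
  # (iii)/(iv) removals
  expect_false("GLYCK" %in% r$id)
  expect_false("EX_fe2_e" %in% r$id)
  # (v) threonine cleavage blocked
  expect_equal(r$lower_bound[r$id == "THRA"], 0)
  expect_equal(r$upper_bound[r$id == "THRA"], 0)
  # idempotence
  cur2 <- suppressWarnings(applyCurations(cur))
  expect_equal(reactions(cur2), reactions(cur))
  expect_equal(as.matrix(stoichiometry(cur2)), as.matrix(stoichiometry(cur)))
})

test_that("a model lacking all curation targets passes through with warnings", {
  w <- capture_warnings(applyCurations(toyNoRoute()))
  expect_length(w, 8)
  out <- suppressWarnings(applyCurations(toyNoRoute()))
  expect_equal(reactions(out), reactions(toyNoRoute()))
})

test_that("variant construction applies the declared blocks and additions", {
  ged <- suppressWarnings(makeVariant(curatedNet, "GED_shunt"))
  r <- reactions(ged)
  expect_equal(r$lower_bound[r$id == "GND"], -1000)
  for (id in c("PFK", "FBP", "ZWF")) {  # G6PDH2r resolves to ZWF
    expect_equal(r$lower_bound[r$id == id], 0)
    expect_equal(r$upper_bound[r$id == id], 0)
  }
  # WT spec leaves the curated model unchanged
  wt <- makeVariant(curatedNet, "WT")
  expect_equal(reactions(wt), reactions(curatedNet))
  # RuBP shunt adds PRK and RBPC with the same blocks
  rub <- suppressWarnings(makeVariant(curatedNet, "RuBP_shunt"))
  expect_true(all(c("PRK", "RBPC") %in% reactionIds(rub)))
  rr <- reactions(rub)
  expect_equal(rr$upper_bound[rr$id == "PFK"], 0)
  expect_equal(rr$lower_bound[rr$id == "GND"], 0)  # Gnd stays irreversible
  # adding PRK to a model that already has it is an error
  expect_error(suppressWarnings(
    makeVariant(suppressWarnings(applyCurations(coreNetRubp)), "RuBP_shunt")),
    "already exists")
})

test_that("anaerobic glucose fermentation is homolactate at 2 mol/mol", {
  cfg <- fbaConfig(substrate = "EX_glc__D_e", uptake = 13.1,
                   product = "EX_lac__D_e")
  y <- maxProductYield(curatedNet, cfg)
  expect_equal(y@yield, 2, tolerance = 1e-6)
})

test_that("an absent substrate is an error", {
  cfg <- fbaConfig(substrate = "EX_sucrose_e", product = "EX_ac_e")
  expect_error(maxProductYield(curatedNet, cfg), "sucrose")
})

test_that("the FBA optimum is feasible by substitution and carbon-closed", {
  cfg <- fbaConfig(substrate = "EX_xyl__D_e", uptake = 10.8,
                   product = "EX_ac_e")
  ged <- suppressWarnings(makeVariant(curatedNet, "GED_shunt"))
  y <- maxProductYield(ged, cfg)
  v <- y@fluxes
  S <- stoichiometry(ged)[, names(v)]
  expect_lt(max(abs(as.numeric(S %*% v))), 1e-6)
  # carbon conservation: summed carbon of all exchange fluxes is zero
  r <- reactions(ged)
  m <- metabolites(ged)
  ex <- r$id[r$is_exchange]
  carbonFlux <- sum(vapply(ex, function(id) {
    sto <- reactionStoichiometry(ged, id)
    -v[[id]] * m$carbons[m$id == names(sto)]
  }, numeric(1)))
  expect_equal(carbonFlux, 0, tolerance = 1e-6)
})

test_that("the GED shunt matches or beats the RuBP shunt on every product", {
  products <- c("EX_ac_e", "EX_lac__D_e", "EX_etoh_e", "EX_pyr_e")
  for (h2 in c(FALSE, TRUE)) {
    tab <- suppressWarnings(relativeYieldTable(
      curatedNet, c("GED_shunt", "RuBP_shunt"), products,
      fbaConfig(h2_donor = h2)))
    ged <- tab$yield[tab$variant == "GED_shunt"]
    rub <- tab$yield[tab$variant == "RuBP_shunt"]
    expect_true(all(ged >= rub - 1e-9))
  }
})

test_that("an ATP-limited product separates the shunts strictly", {
  # pyruvate yields no substrate-level ATP downstream of the shunt, so the
  # RuBP route must divert carbon to pay the maintenance cost
  cfg <- fbaConfig(product = "EX_pyr_e")
  ged <- maxProductYield(suppressWarnings(makeVariant(curatedNet,
                                                      "GED_shunt")), cfg)
  rub <- maxProductYield(suppressWarnings(makeVariant(curatedNet,
                                                      "RuBP_shunt")), cfg)
  expect_gt(ged@yield, rub@yield + 0.1)
})

test_that("an auxiliary H2 electron donor strictly raises the GED lactate yield", {
  ged <- suppressWarnings(makeVariant(curatedNet, "GED_shunt"))
  noH2 <- maxProductYield(ged, fbaConfig(product = "EX_lac__D_e"))
  withH2 <- maxProductYield(ged, fbaConfig(product = "EX_lac__D_e",
                                           h2_donor = TRUE))
  expect_gt(withH2@yield, noH2@yield + 0.1)
})

test_that("relative yields are 1 for WT and NA for a zero-yield product", {
  tab <- suppressWarnings(relativeYieldTable(
    curatedNet, character(), c("EX_ac_e", "EX_lac__D_e")))
  expect_true(all(tab$relative_yield[tab$variant == "WT"] == 1))
  # formate cannot be made aerobically here (PFL blocked, no other source)
  tab2 <- suppressWarnings(relativeYieldTable(
    curatedNet, "GED_shunt", "EX_for_e",
    fbaConfig(aerobic = TRUE)))
  expect_true(all(tab2$yield == 0))
  expect_true(all(is.na(tab2$relative_yield)))
})

test_that("blocking a reaction never increases the maximal yield", {
  cfg <- fbaConfig(substrate = "EX_glc__D_e", uptake = 13.1,
                   product = "EX_ac_e")
  base <- maxProductYield(curatedNet, cfg)@yield
  for (id in c("PFK", "GAPD", "PTAr")) {
    blocked <- latentpath:::.setBounds(curatedNet, id, 0, 0)
    y <- tryCatch(maxProductYield(blocked, cfg)@yield,
                  error = function(e) 0)
    expect_lte(y, base + 1e-9)
  }
})

test_that("byproduct secretions are reported above the threshold", {
  cfg <- fbaConfig(substrate = "EX_glc__D_e", uptake = 13.1,
                   product = "EX_ac_e")
  y <- maxProductYield(curatedNet, cfg)
  expect_gt(length(y@byproducts), 0)
  expect_true(all(y@byproducts > 1e-6))
  expect_false(y@product %in% names(y@byproducts))
})
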