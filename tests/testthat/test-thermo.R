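# Transformed Gibbs energies, Henry conversions and the MDF linear program.

test_that("Gnd is nearly reversible at 1 mM reactants and 200 mbar CO2", {
  dgm <- transformDg(coreNet, "GND")
  expect_lt(abs(dgm - (-1.5)), 0.5)
})

test_that("transformDg identities hold", {
  # all references 1 M on a reaction with no fixed participants: dG'0 back
  expect_equal(transformDg(coreNet, "PGI", reference = 1),
               reactions(coreNet)$dg0_prime[reactionIds(coreNet) == "PGI"])
  # reversing a reaction negates the transformed energy
  mets <- data.frame(id = c("a_c", "b_c"), carbons = c(1L, 1L))
  fwd <- MetabolicNetwork(mets, data.frame(id = "R", dg0_prime = 3.2),
                          list(R = c(a_c = -1, b_c = 2)))
  rev <- MetabolicNetwork(mets, data.frame(id = "R", dg0_prime = -3.2),
                          list(R = c(a_c = 1, b_c = -2)))
  ref <- c(a_c = 2e-3, b_c = 5e-5)
  expect_equal(transformDg(fwd, "R", reference = ref),
               -transformDg(rev, "R", reference = ref))
  # missing dG'0 and missing reference are reported
  expect_error(transformDg(coreNet, "GLCt"), "no dG'0")
  expect_error(transformDg(fwd, "R", reference = c(a_c = 1e-3)), "b_c")
})

test_that("Keq conversions are exact inverses and match the isomerase value", {
  expect_equal(keqFromDg(0), 1)
  expect_equal(dgFromKeq(0.458), 1.9358, tolerance = 1e-4)
  for (x in c(-30, -1.5, 0, 2.7, 40)) {
    expect_equal(dgFromKeq(keqFromDg(x)), x, tolerance = 1e-9)
  }
})

test_that("Henry conversions: 0.9 mM dissolved CO2 is ~3% headspace", {
  expect_equal(co2PressureToConc(0), 0)
  expect_equal(co2PressureToConc(200), 6.76e-3, tolerance = 1e-12)
  expect_equal(round(co2HeadspacePercent(0.9e-3)), 3)
  expect_equal(co2ConcToPressure(co2PressureToConc(123.4)), 123.4,
               tolerance = 1e-12)
  expect_error(co2PressureToConc(-1), "negative")
})

test_that("single-reaction MDF matches the closed form on both engines", {
  toy <- MetabolicNetwork(
    metabolites = data.frame(id = c("a_c", "b_c"), carbons = c(1L, 1L)),
    reactions = data.frame(id = "R1", dg0_prime = 0),
    stoichiometry = list(R1 = c(a_c = -1, b_c = 1)))
  expected <- 0.008314 * 298.15 * log(1e4)   # RT ln(ub_A / lb_B)
  for (engine in c("highs", "simplex")) {
    res <- computeMdf(toy, "R1", engine = engine)
    expect_equal(res@mdf, expected, tolerance = 1e-6)
    expect_identical(res@bottlenecks, "R1")
  }
})

test_that("fully fixed concentrations reduce MDF to -dG'", {
  toy <- MetabolicNetwork(
    metabolites = data.frame(id = c("a_c", "b_c"), carbons = c(1L, 1L),
                             fixed_conc = c(1, 1)),
    reactions = data.frame(id = "R1", dg0_prime = -10),
    stoichiometry = list(R1 = c(a_c = -1, b_c = 1)))
  expect_equal(computeMdf(toy, "R1")@mdf, 10, tolerance = 1e-9)
})

test_that("two-reaction chain MDF equals the hand-derived analytic optimum", {
  # A -> B -> C with dg1 = 5, dg2 = -3: the optimum pins x_A at its upper
  # and x_C at its lower bound and balances x_B, so
  #   B* = (-(dg1 + dg2) + RT ln(ub/lb)) / 2
  toy <- MetabolicNetwork(
    metabolites = data.frame(id = c("a_c", "b_c", "c_c"),
                             carbons = c(1L, 1L, 1L)),
    reactions = data.frame(id = c("R1", "R2"), dg0_prime = c(5, -3)),
    stoichiometry = list(R1 = c(a_c = -1, b_c = 1),
                         R2 = c(b_c = -1, c_c = 1)))
  RT <- 0.008314 * 298.15
  analytic <- (-(5) - (-3) + RT * log(1e4)) / 2
  res <- computeMdf(toy, c("R1", "R2"))
  expect_equal(res@mdf, analytic, tolerance = 1e-6)
  expect_setequal(res@bottlenecks, c("R1", "R2"))
  expect_equal(computeMdf(toy, c("R1", "R2"), engine = "simplex")@mdf,
               analytic, tolerance = 1e-6)
})

test_that("MDF optimum is feasible by substitution", {
  res <- computeMdf(prepNet, fixturePathway("ged_cycle", prepNet))
  expect_true(all(-res@reactionDgPrime >= res@mdf - 1e-6))
  lo <- log(1e-6) - 1e-9; hi <- log(1e-2) + 1e-9
  free <- setdiff(names(res@logConcentrations), c("co2_c", "o2_c"))
  expect_true(all(res@logConcentrations[free] >= lo &
                  res@logConcentrations[free] <= hi))
})

test_that("adding a reaction constraint never increases MDF", {
  withDg <- reactionIds(prepNet)[!is.na(reactions(prepNet)$dg0_prime) &
                                   !reactions(prepNet)$is_pseudo]
  set.seed(42)
  for (i in 1:25) {
    ids <- sample(withDg, sample(2:5, 1))
    dirs <- sample(c(-1, 1), length(ids), replace = TRUE)
    sup <- data.frame(id = ids, direction = dirs)
    full <- computeMdf(prepNet, sup, engine = "simplex")@mdf
    part <- computeMdf(prepNet, sup[-1, ], engine = "simplex")@mdf
    expect_lte(full, part + 1e-7)
  }
})

test_that("widening concentration bounds never decreases MDF", {
  sup <- fixturePathway("ged_cycle", prepNet)
  narrow <- computeMdf(prepNet, sup,
                       concentrationBounds(1e-5, 1e-3))@mdf
  wide <- computeMdf(prepNet, sup, concentrationBounds(1e-6, 1e-2))@mdf
  wider <- computeMdf(prepNet, sup, concentrationBounds(1e-7, 1e-1))@mdf
  expect_lte(narrow, wide + 1e-7)
  expect_lte(wide, wider + 1e-7)
})

test_that("MDF errors are informative", {
  expect_error(computeMdf(coreNet, "GLCt"), "missing dG'0")
  expect_error(computeMdf(coreNet, character()), "unbounded|constraining")
  expect_error(
    computeMdf(coreNet, "PGI", concentrationBounds(
      overrides = list(g6p_c = c(2e-3, 1e-3)))),
    "")
})
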