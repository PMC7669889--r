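# MILP pathway enumeration, Pareto ranking, net conversion, ATP accounting.

gedExpected <- c("GND", "EDD", "EDA", "PPS", "ENO", "PGM", "PGK", "GAPD",
                 "TPI", "FBA", "FBP", "TKT1", "TKT2", "TALA", "RPE", "RPI")

fixtureEnum <- enumeratePathways(coreNet, maxSolutions = 6)

test_that("the fixture's top-ranked pathway is the GED cycle", {
  expect_gt(length(fixtureEnum), 0)
  top <- fixtureEnum[[1]]
  expect_setequal(pathwaySupport(top)$id, gedExpected)
  # reductive carboxylation by Gnd, ED pathway forward
  sup <- pathwaySupport(top)
  expect_equal(sup$direction[sup$id == "GND"], -1)
  expect_equal(sup$direction[sup$id == "EDD"], 1)
  expect_equal(sup$direction[sup$id == "EDA"], 1)
  expect_gt(mdf(top), 3)
  expect_equal(pathwaySize(top), 16)
})

test_that("every enumerated pathway is feasible, positive-MDF and 3:1", {
  for (p in fixtureEnum) {
    expect_gt(mdf(p), 0)
    nc <- netConversion(p, prepNet)
    expect_equal(unname(nc["co2_c"]), -3, tolerance = 1e-6)
    expect_equal(unname(nc["pyr_c"]), 1, tolerance = 1e-6)
    # carbon balance of the conversion: 3 x 1 carbon in, 1 x 3 carbons out
    m <- metabolites(prepNet)
    carb <- sum(nc * m$carbons[match(names(nc), m$id)])
    expect_equal(carb, 0, tolerance = 1e-6)
    # exact-LP certificate agrees with the stored value
    expect_equal(computeMdf(prepNet, p)@mdf, mdf(p), tolerance = 1e-6)
  }
})

test_that("integer cuts yield pairwise distinct directed supports", {
  keys <- vapply(fixtureEnum, supportKey, character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("pseudo-reactions never appear in reported supports", {
  for (p in fixtureEnum) {
    expect_false(any(grepl("^PSEUDO_", pathwaySupport(p)$id)))
  }
})

test_that("a single-route toy yields exactly that route (oracle agreement)", {
  toy <- toySingleRoute()
  mi <- enumeratePathways(toy, maxSolutions = 20)
  bf <- bruteForceEnumerate(toy)
  expect_length(mi, 1)
  expect_length(bf, 1)
  expect_equal(supportKey(mi[[1]]), "R1:1;R2:1")
  expect_equal(supportKey(bf[[1]]), "R1:1;R2:1")
  expect_equal(unname(pathwayFluxes(mi[[1]])[c("R1", "R2")]), c(3, 1),
               tolerance = 1e-6)
})

test_that("an unreachable product gives an empty enumeration", {
  expect_length(enumeratePathways(toyNoRoute(), maxSolutions = 5), 0)
  expect_length(bruteForceEnumerate(toyNoRoute()), 0)
})

test_that("maxSolutions = 0 returns an empty list", {
  expect_length(enumeratePathways(coreNet, maxSolutions = 0), 0)
})

test_that("Pareto front keeps exactly the non-dominated pathways", {
  df <- data.frame(n_reactions = c(5, 6, 7), mdf = c(2, 5, 4))
  front <- paretoFront(df)
  expect_equal(front$n_reactions, c(5, 6))
  single <- data.frame(n_reactions = 9, mdf = 1)
  expect_equal(paretoFront(single), single)
  # ties on both coordinates are all kept
  ties <- data.frame(n_reactions = c(4, 4), mdf = c(3, 3))
  expect_equal(nrow(paretoFront(ties)), 2)
})

test_that("the fixture Pareto front is the GED cycle alone", {
  front <- paretoFront(fixtureEnum)
  expect_length(front, 1)
  expect_setequal(pathwaySupport(front[[1]])$id, gedExpected)
})

test_that("removing oxygen-sensitive reactions leaves the GED front intact", {
  enum2 <- enumeratePathways(coreNet, maxSolutions = 6,
                             excludeOxygenSensitive = TRUE)
  front <- paretoFront(enum2)
  expect_length(front, 1)
  expect_setequal(pathwaySupport(front[[1]])$id, gedExpected)
})

test_that("the objective weight does not move the fixture Pareto front", {
  frontKeys <- function(w) {
    sort(vapply(paretoFront(enumeratePathways(coreNet, maxSolutions = 5,
                                              w = w)),
                supportKey, character(1)))
  }
  ref <- frontKeys(1)
  expect_equal(frontKeys(0.5), ref)
  expect_equal(frontKeys(2), ref)
})

test_that("net conversion of the named fixture cycles is 3 CO2 -> 1 pyruvate", {
  ged <- fixturePathway("ged_cycle", prepNet)
  expect_equal(unname(netConversion(ged, prepNet)[c("co2_c", "pyr_c")]),
               c(-3, 1), tolerance = 1e-9)
  rub <- fixturePathway("rubp_cycle", prepNetRubp)
  expect_equal(unname(netConversion(rub, prepNetRubp)[c("co2_c", "pyr_c")]),
               c(-3, 1), tolerance = 1e-9)
  # empty pathway: empty mapping
  empty <- new("CandidatePathway", support = data.frame(id = character(),
                                                        direction = numeric()),
               fluxes = setNames(numeric(), character()),
               netConversion = setNames(numeric(), character()),
               mdf = NA_real_, nReactions = 0L)
  expect_length(netConversion(empty, prepNet), 0)
})

test_that("ATP accounting gives 6 for the GED cycle and 7 for the RuBP cycle", {
  ged <- fixturePathway("ged_cycle", prepNet)
  expect_equal(atpCost(ged, prepNet), 6, tolerance = 1e-9)
  rub <- fixturePathway("rubp_cycle", prepNetRubp)
  expect_equal(atpCost(rub, prepNetRubp), 7, tolerance = 1e-9)
  empty <- new("CandidatePathway", support = data.frame(id = character(),
                                                        direction = numeric()),
               fluxes = setNames(numeric(), character()),
               netConversion = setNames(numeric(), character()),
               mdf = NA_real_, nReactions = 0L)
  expect_equal(atpCost(empty, prepNet), 0)
  # an adenylate missing from the accounting table is an error
  expect_error(atpCost(ged, prepNet, accounting = c(atp = 2)), "amp|adp")
})

test_that("MILP enumeration agrees with the brute-force oracle on random nets", {
  for (seed in 1:6) {
    net <- randomNetwork(nMetabolites = 7, nReactions = 7, seed = seed)
    kb <- sort(vapply(bruteForceEnumerate(net), supportKey, character(1)))
    km <- sort(vapply(enumeratePathways(net, maxSolutions = 50),
                      supportKey, character(1)))
    expect_equal(km, kb, info = paste("seed", seed))
  }
})

test_that("the size cap of the brute-force oracle is enforced", {
  expect_error(bruteForceEnumerate(coreNet, maxReactions = 12), "too large")
})
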