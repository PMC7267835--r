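test_that("carbon counting parses Hill-notation formulas", {
  expect_equal(carbonCount("C6H12O6"), 6)
  expect_equal(carbonCount("H2O"), 0)
  expect_equal(carbonCount("C10H12N5O13P3"), 10)
  expect_equal(carbonCount("CO2"), 1)          # implicit count of 1
  expect_equal(carbonCount(c("C2H4", "CaCO3")), c(2, 1))  # Ca is not carbon
  expect_warning(expect_equal(carbonCount(""), 0), "empty")
  expect_error(suppressWarnings(carbonCount("C6?x")), "malformed")
})

test_that("dead-end removal prunes blocked branches and preserves growth", {
  # extend toy5 with DX: C -> D where D has no consumer
  mets <- c(metaboliteIds(toy5), "D")
  S <- rbind(cbind(as.matrix(stoichiometry(toy5)), 0), 0)
  S[3, 6] <- -1; S[4, 6] <- 1
  ext <- MetabolicModel(mets, c(reactionIds(toy5), "DX"), S,
                        c(toy5@lb, 0), c(toy5@ub, 1000),
                        biomassIndex = "BIO",
                        formulas = c(toy5@formulas, ""))
  de <- removeDeadEnds(ext)
  expect_equal(de$removed, "DX")
  expect_false("D" %in% metaboliteIds(de$model))
  expect_equal(solveFBA(de$model)@objectiveValue,
               solveFBA(ext)@objectiveValue, tolerance = 1e-9)
  # toy5 itself has no dead ends
  expect_length(removeDeadEnds(toy5)$removed, 0)
  # property: biomass optimum invariant on random fixtures
  for (s in 1:3) {
    m <- makeToyNetwork("random_branched", nBranches = 2 + s, seed = s)
    expect_equal(solveFBA(removeDeadEnds(m)$model)@objectiveValue,
                 solveFBA(m)@objectiveValue, tolerance = 1e-8)
  }
})

test_that("linear-chain compression merges unbranched paths only", {
  S <- matrix(0, 2, 3, dimnames = list(c("X", "Y"), c("Ra", "Rb", "Rc")))
  S["X", "Ra"] <- 1; S["X", "Rb"] <- -1
  S["Y", "Rb"] <- 1; S["Y", "Rc"] <- -1
  chain <- MetabolicModel(c("X", "Y"), c("Ra", "Rb", "Rc"), S,
                          c(0, 0, 0), c(10, 10, 10), biomassIndex = "Rc")
  cc <- compressLinearChains(chain, protect = "Rc")
  expect_equal(nReactions(cc$model), 2)
  expect_setequal(cc$mapping[["Ra__Rb"]], c("Ra", "Rb"))
  expect_equal(solveFBA(cc$model)@objectiveValue, 10, tolerance = 1e-9)
  # toy5: A has two consumers, sinks are protected -> nothing merges
  cc5 <- compressLinearChains(toy5)
  expect_equal(nReactions(cc5$model), 5)
  # property: FBA optimum invariant under compression
  for (s in 4:6) {
    m <- makeToyNetwork("random_branched", nBranches = 2 + s %% 3, seed = s)
    cm <- compressLinearChains(m)
    expect_equal(solveFBA(cm$model)@objectiveValue,
                 solveFBA(m)@objectiveValue, tolerance = 1e-8)
    # mapping covers every original reaction exactly once
    expect_setequal(unlist(cm$mapping), reactionIds(m))
  }
})

test_that("essentiality screen flags exactly the unavoidable reactions", {
  expect_setequal(essentialReactions(toy5, 1), c("UP", "BIO"))
  expect_length(essentialReactions(toy5, 0), 0)
  # R1 and R3 are mutually redundant, so neither is essential alone
  expect_false(any(c("R1", "R3") %in% essentialReactions(toy5, 1)))
})

test_that("candidate selection applies the exclusion rules in order", {
  # carbon filter: C (C40H56) touches R3 and PRD
  c10 <- suppressMessages(selectCandidates(toy5, "PRD", nC = 10,
                                           growthFloor = 1,
                                           requireGeneRule = FALSE))
  expect_equal(reactionIds(toy5)[c10@indices], "R1")
  c100 <- suppressMessages(selectCandidates(toy5, "PRD", nC = 100,
                                            growthFloor = 1,
                                            requireGeneRule = FALSE))
  expect_setequal(reactionIds(toy5)[c100@indices], c("R1", "R3"))
  # excluding an absent reaction warns but leaves the set unchanged
  expect_warning(
    cx <- suppressMessages(selectCandidates(toy5, "PRD", nC = 100,
                                            growthFloor = 1,
                                            requireGeneRule = FALSE,
                                            userExcludes = "NOPE")),
    "NOPE")
  expect_equal(cx@indices, c100@indices)
  expect_error(
    suppressMessages(selectCandidates(toy5, "PRD", nC = 0, growthFloor = 1,
                                      requireGeneRule = FALSE)),
    "larger carbon cutoff")
})

test_that("candidate sets grow monotonically with the carbon cutoff", {
  for (s in c(2, 5)) {
    m <- makeToyNetwork("random_branched", nBranches = 3, seed = s)
    floor <- 0.1 * solveFBA(m)@objectiveValue
    prev <- integer()
    for (nc in c(3, 5, 100)) {
      cs <- suppressMessages(
        selectCandidates(m, "PRD", nC = nc, growthFloor = floor))
      expect_true(all(prev %in% cs@indices))
      prev <- cs@indices
      # no candidate is essential at the floor
      expect_false(any(reactionIds(m)[cs@indices] %in%
                         essentialReactions(m, floor)))
      # biomass and target are never candidates
      expect_false(biomassReaction(m) %in% cs@indices)
      expect_false(match("PRD", reactionIds(m)) %in% cs@indices)
    }
  }
})

test_that("the oxygen exchange is kept as a candidate when requested", {
  # toy-like net with an O2 exchange: OX: -> O2, RESP: A + O2 -> B
  mets <- c("A", "B", "O2")
  rxns <- c("UP", "OX", "RESP", "FERM", "BIO")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A", "UP"] <- 1; S["O2", "OX"] <- 1
  S["A", "RESP"] <- -1; S["O2", "RESP"] <- -1; S["B", "RESP"] <- 1
  S["A", "FERM"] <- -1; S["B", "FERM"] <- 1
  S["B", "BIO"] <- -1
  m <- MetabolicModel(mets, rxns, S, numeric(5), c(10, 10, 1000, 1000, 1000),
                      biomassIndex = "BIO",
                      formulas = c("C3H4O3", "C3H7NO2", "O2"),
                      geneRules = c("", "", "g1", "g2", ""))
  keep <- suppressMessages(selectCandidates(m, "FERM", growthFloor = 0,
                                            keepOxygen = TRUE,
                                            requireGeneRule = FALSE))
  expect_true("OX" %in% reactionIds(m)[keep@indices])
  drop <- suppressMessages(selectCandidates(m, "FERM", growthFloor = 0,
                                            keepOxygen = FALSE,
                                            requireGeneRule = FALSE))
  expect_false("OX" %in% reactionIds(m)[drop@indices])
})
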