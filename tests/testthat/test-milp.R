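test_that("penalty sampling is reproducible and respects its interval", {
  M <- samplePenalties(50, seed = 2020)
  expect_true(all(M >= 90 & M <= 110))
  expect_identical(M, samplePenalties(50, seed = 2020))
  expect_false(identical(as.numeric(M), as.numeric(samplePenalties(50, seed = 7))))
  expect_equal(as.numeric(samplePenalties(5, low = 100, high = 100)),
               rep(100, 5))
})

test_that("the Lagrangian follower LP equals the direct inner LP on designs
           where the penalty binds", {
  cand <- toy5Candidates()
  M <- samplePenalties(length(cand))
  r1 <- designVector("R1", reactionIds(toy5)[cand@indices], K = 1,
                     model = toy5)
  flp <- buildFollowerLP(toy5, "PRD", M, r1, growthFloor = 1)
  sol <- solveFollowerLP(flp)
  expect_equal(sol$value, 1, tolerance = 1e-8)
  expect_lt(abs(sol$v[2]), 1e-8)   # v_R1 forced to zero by the penalty
  expect_lt(abs(sol$u[2]), 1e-8)
  # empty design: penalty term vanishes, plain inner minimum
  none <- designVector(character(), reactionIds(toy5)[cand@indices],
                       K = 1, model = toy5)
  expect_equal(solveFollowerLP(
    buildFollowerLP(toy5, "PRD", M, none, 1))$value, 0, tolerance = 1e-9)
})

test_that("follower reformulation is equivalent across random designs", {
  worst <- 0
  for (fx in fixtureGrid(1:4)) {
    M <- samplePenalties(length(fx$cand))
    for (d in randomDesigns(fx$cand, fx$K, 12, seed = 50 + fx$seed)) {
      direct <- followerMinProduction(fx$model, "PRD", d, fx$floor)
      lag <- solveFollowerLP(
        buildFollowerLP(fx$model, "PRD", M, d, fx$floor))
      expect_equal(lag$status == "optimal", direct@status == "optimal")
      if (direct@status == "optimal") {
        worst <- max(worst, abs(lag$value - direct@objectiveValue))
        ko <- which(d@y == 1)
        if (length(ko))
          expect_lt(max(abs(lag$v[d@candidates[ko]])), 1e-6)
      }
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("the single-level MILP solves toy5 exactly", {
  cand <- toy5Candidates()
  milp <- buildSingleLevelMILP(toy5, cand, "PRD", K = 1, growthFloor = 1)
  res <- solveDirect(milp)
  expect_equal(res$status, "optimal")
  expect_equal(res$value, 1, tolerance = 1e-6)
  expect_equal(reactionIds(toy5)[knockedReactions(res$design)], "R1")
  expect_lt(strongDualityResidual(milp, res$x), 1e-6)
  # K = 0 forces the wild-type inner minimum
  m0 <- buildSingleLevelMILP(toy5, cand, "PRD", K = 0, growthFloor = 1)
  expect_equal(solveDirect(m0)$value, 0, tolerance = 1e-8)
  # candidates {R3} only: both remaining designs attain 0
  c3 <- candidateSet(match("R3", reactionIds(toy5)))
  m3 <- buildSingleLevelMILP(toy5, c3, "PRD", K = 1, growthFloor = 1)
  expect_equal(solveDirect(m3)$value, 0, tolerance = 1e-8)
})

test_that("the MILP rejects candidates overlapping biomass or target", {
  expect_error(buildSingleLevelMILP(toy5, candidateSet(c(2L, 4L)), "PRD",
                                    K = 1),
               "exclude the biomass")
})

test_that("brute force enumerates toy5 correctly", {
  cand <- toy5Candidates()
  bf1 <- bruteForceInterdiction(toy5, cand, 1, "PRD", 1)
  expect_equal(bf1$bestValue, 1, tolerance = 1e-9)
  expect_equal(reactionIds(toy5)[knockedReactions(bf1$bestDesigns[[1]])],
               "R1")
  # K = 2: {R1, R3} is infeasible, the optimum stays at {R1}
  bf2 <- bruteForceInterdiction(toy5, cand, 2, "PRD", 1)
  expect_equal(bf2$bestValue, 1, tolerance = 1e-9)
  expect_length(bf2$bestDesigns, 1)
  bf0 <- bruteForceInterdiction(toy5, cand, 0, "PRD", 1)
  expect_equal(bf0$bestValue, 0, tolerance = 1e-12)
  expect_length(knockedReactions(bf0$bestDesigns[[1]]), 0)
  big <- candidateSet(seq_len(4))
  expect_error(bruteForceInterdiction(makeToyNetwork("random_branched",
                                                     nBranches = 30, seed = 1),
                                      candidateSet(2:61), 4, "PRD", 0),
               "runHBA")
})

test_that("direct MILP agrees with brute force; optimum is sandwiched and
           monotone in K; penalties force knocked fluxes to zero", {
  for (fx in fixtureGrid(1:6)) {
    bf <- bruteForceInterdiction(fx$model, fx$cand, fx$K, "PRD", fx$floor)
    milp <- buildSingleLevelMILP(fx$model, fx$cand, "PRD", fx$K,
                                 growthFloor = fx$floor)
    res <- solveDirect(milp)
    expect_equal(res$value, bf$bestValue, tolerance = 1e-5)
    expect_lt(strongDualityResidual(milp, res$x), 1e-6)
    tmp <- theoreticalMaxProduction(fx$model, "PRD")
    expect_gte(res$value, -1e-9)
    expect_lte(res$value, tmp + 1e-6)
    # penalty sufficiency at the optimum
    ko <- which(res$y == 1)
    if (length(ko)) {
      v <- res$x[milp@blocks$v]
      expect_lt(max(abs(v[milp@candidates[ko]])), 1e-6)
    }
    # monotonicity in K (brute force)
    if (fx$K > 1) {
      bfSmall <- bruteForceInterdiction(fx$model, fx$cand, fx$K - 1, "PRD",
                                        fx$floor)
      expect_lte(bfSmall$bestValue, bf$bestValue + 1e-9)
    }
  }
})

test_that("the LP-format writer emits a parseable, complete file", {
  cand <- toy5Candidates()
  milp <- buildSingleLevelMILP(toy5, cand, "PRD", K = 1, growthFloor = 1)
  path <- tempfile(fileext = ".lp")
  writeMilpLp(milp, path)
  txt <- readLines(path)
  expect_true(any(grepl("^Maximize$", txt)))
  expect_true(any(grepl("^Binary$", txt)))
  expect_true(any(grepl("bud:", txt)))
  expect_equal(sum(grepl("^ eq", txt)), nMetabolites(toy5))
  expect_equal(sum(grepl("^ le", txt)), nrow(milp@A))
})
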