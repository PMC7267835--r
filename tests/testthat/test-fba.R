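test_that("FBA reproduces the hand-computed toy5 optima", {
  expect_equal(solveFBA(toy5)@objectiveValue, 10, tolerance = 1e-9)
  expect_equal(solveFBA(toy5, "PRD", "min")@objectiveValue, 0, tolerance = 1e-9)
  zero <- toy5; zero@lb[] <- 0; zero@ub[] <- 0
  expect_equal(solveFBA(zero)@objectiveValue, 0, tolerance = 1e-12)
  # steady state and bounds hold at the optimum
  sol <- solveFBA(toy5)
  expect_lt(max(abs(as.numeric(stoichiometry(toy5) %*% sol@v))), 1e-6)
  expect_true(all(sol@v >= toy5@lb - 1e-9 & sol@v <= toy5@ub + 1e-9))
})

test_that("LP duality holds: primal optimum equals the explicit dual optimum", {
  models <- c(list(toy5), lapply(1:3, function(s)
    makeToyNetwork("random_branched", nBranches = 2 + s, seed = s)))
  for (m in models) {
    n <- nReactions(m); obj <- numeric(n); obj[biomassReaction(m)] <- 1
    primal <- solveFBA(m)
    # dual of max c'v, Sv=0, l<=v<=u:  min u'p - l'q  s.t. S'lam + p - q = c
    St <- Matrix::t(stoichiometry(m))
    nm <- nMetabolites(m)
    Aeq <- cbind(St, Matrix::Diagonal(n), -Matrix::Diagonal(n))
    dual <- lpSolveRaw(c(numeric(nm), m@ub, -m@lb), "min",
                       Aeq = Aeq, beq = obj,
                       lower = c(rep(-Inf, nm), numeric(2 * n)),
                       upper = rep(Inf, nm + 2 * n))
    expect_equal(primal@objectiveValue, dual$objective, tolerance = 1e-6)
  }
})

test_that("theoretical maximum production matches the rerouted optimum and
           bounds every design's guaranteed minimum", {
  expect_equal(theoreticalMaxProduction(toy5, "PRD"), 10, tolerance = 1e-9)
  blocked <- toy5; blocked@ub[5] <- 0
  expect_equal(theoreticalMaxProduction(blocked, "PRD"), 0, tolerance = 1e-12)
  for (fx in fixtureGrid(1:3)) {
    tmp <- theoreticalMaxProduction(fx$model, "PRD")
    for (d in randomDesigns(fx$cand, fx$K, 10, seed = fx$seed)) {
      sol <- followerMinProduction(fx$model, "PRD", d, fx$floor)
      if (sol@status == "optimal") {
        expect_gte(sol@objectiveValue, -1e-9)
        expect_lte(sol@objectiveValue, tmp + 1e-6)
      }
    }
  }
})

test_that("the follower LP is the design evaluation oracle on toy5", {
  cand <- c("R1", "R3")
  none <- designVector(character(), cand, K = 2, model = toy5)
  expect_equal(followerMinProduction(toy5, "PRD", none, 1)@objectiveValue, 0,
               tolerance = 1e-9)
  r1 <- designVector("R1", cand, K = 2, model = toy5)
  expect_equal(followerMinProduction(toy5, "PRD", r1, 1)@objectiveValue, 1,
               tolerance = 1e-9)
  both <- designVector(c("R1", "R3"), cand, K = 2, model = toy5)
  expect_equal(followerMinProduction(toy5, "PRD", both, 1)@status,
               "infeasible")
})

test_that("production envelopes match the hand LP and classify coupling", {
  r1 <- designVector("R1", c("R1", "R3"), K = 1, model = toy5)
  env <- productionEnvelope(toy5, "PRD", r1, nPoints = 3)
  expect_equal(env@biomassGrid, c(0, 5, 10))
  expect_equal(env@minProduction, c(0, 5, 10), tolerance = 1e-8)
  expect_equal(env@maxProduction, c(0, 5, 10), tolerance = 1e-8)
  expect_equal(env@couplingClass, "growth_coupled")
  wt <- productionEnvelope(toy5, "PRD", nPoints = 3)
  expect_equal(wt@minProduction[3], 0, tolerance = 1e-9)   # min at opt growth
  expect_equal(wt@maxProduction[3], 10, tolerance = 1e-8)  # R3 free at b = 10
  expect_equal(wt@couplingClass, "none")
  both <- designVector(c("R1", "R3"), c("R1", "R3"), K = 2, model = toy5)
  # zero-growth-only model still has an envelope (single point at 0)
  expect_error(productionEnvelope(applyKnockouts(toy5, "UP"), "PRD", both),
               NA)
})

test_that("coupling classification follows the envelope definition", {
  mk <- function(minProd, maxProd = pmax(minProd, 6)) {
    new("EnvelopeCurve", biomassGrid = c(0, 1), minProduction = minProd,
        maxProduction = maxProd, couplingClass = "none")
  }
  expect_equal(classifyCoupling(mk(c(2, 2))), "strong")
  expect_equal(classifyCoupling(mk(c(0, 5))), "growth_coupled")
  expect_equal(classifyCoupling(mk(c(0, 0))), "none")
})

test_that("knockout envelopes nest inside the wild-type envelope", {
  for (fx in fixtureGrid(4:6)) {
    wtEnv <- productionEnvelope(fx$model, "PRD", nPoints = 5)
    d <- randomDesigns(fx$cand, fx$K, 1, seed = fx$seed + 100)[[1]]
    ko <- applyKnockouts(fx$model, d)
    if (solveFBA(ko)@status != "optimal") next
    koEnv <- productionEnvelope(fx$model, "PRD", d, nPoints = 5)
    bio <- reactionIds(fx$model)[biomassReaction(fx$model)]
    for (i in seq_along(koEnv@biomassGrid)) {
      b <- koEnv@biomassGrid[i]
      fix <- list(c(b, b)); names(fix) <- bio
      wtMin <- solveFBA(fx$model, "PRD", "min", extraBounds = fix)
      wtMax <- solveFBA(fx$model, "PRD", "max", extraBounds = fix)
      expect_lte(koEnv@maxProduction[i], wtMax@objectiveValue + 1e-6)
      expect_gte(koEnv@minProduction[i], wtMin@objectiveValue - 1e-6)
    }
  }
})

test_that("envelope TSV export round-trips", {
  env <- productionEnvelope(toy5, "PRD", nPoints = 4)
  path <- tempfile(fileext = ".tsv")
  writeEnvelopeTsv(env, path)
  df <- read.delim(path)
  expect_equal(names(df), c("biomass", "min_production", "max_production"))
  expect_equal(df$biomass, env@biomassGrid)
  expect_equal(df$max_production, env@maxProduction)
})
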