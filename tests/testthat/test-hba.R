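test_that("Hamming distance and core-point updates follow the exact
           arithmetic", {
  expect_equal(hammingDistance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(hammingDistance(c(1, 0, 1), c(0, 0, 1)), 1)
  expect_error(hammingDistance(c(1, 0), c(1, 0, 1)), "length")
  set.seed(42)
  for (i in 1:20) {
    a <- rbinom(6, 1, 0.5); b <- rbinom(6, 1, 0.5)
    expect_equal(hammingDistance(a, b), hammingDistance(b, a))
    expect_equal(hammingDistance(a, b), sum(a != b))
  }
  core <- list(yHat = c(0.5, 0.5), mu = 1e-8)
  expect_equal(updateCorePoint(core, c(1, 0))$yHat, c(0.75, 0.25))
  # repeated averaging with 0 halves components but never reaches 0
  c2 <- core
  for (i in 1:60) c2 <- updateCorePoint(c2, c(0, 0))
  expect_true(all(c2$yHat > 0))
  # interiority preserved over random updates from an interior start
  c3 <- corePoint(6, K = 3)
  set.seed(1)
  for (i in 1:100) c3 <- updateCorePoint(c3, rbinom(6, 1, 0.5))
  expect_true(all(c3$yHat > 0 & c3$yHat < 1))
})

test_that("the master early-termination gap schedule is exact", {
  expect_equal(mipGap(0), 301)
  expect_equal(mipGap(4), 101)
  expect_equal(mipGap(10000), 1 + 300 / 101, tolerance = 1e-12)
  expect_true(all(diff(sapply(0:50, mipGap)) < 0))
})

test_that("the master problem honours cuts, caps and branching rows", {
  # no cuts: only the cap binds
  mp <- solveMaster(list(), branchState(c(0L, 0L), r = 3), K = 1, zCap = 10)
  expect_equal(mp$zAtY, 10, tolerance = 1e-9)
  # two crossing optimality cuts on one candidate: max min is 1
  cuts <- list(new("BendersCut", kind = "optimality", constant = 4,
                   coefficients = -3, pi = numeric(), value = NA_real_,
                   yBar = 0L),
               new("BendersCut", kind = "optimality", constant = 1,
                   coefficients = 2, pi = numeric(), value = NA_real_,
                   yBar = 1L))
  mp2 <- solveMaster(cuts, branchState(0L, r = 2), K = 1, zCap = 10)
  expect_equal(mp2$zAtY, 1, tolerance = 1e-9)
  # a feasibility cut 2 - 3 y1 >= 0 forbids y1 = 1
  fc <- new("BendersCut", kind = "feasibility", constant = 2,
            coefficients = -3, pi = numeric(), value = NA_real_, yBar = 1L)
  push <- new("BendersCut", kind = "optimality", constant = 0,
              coefficients = 5, pi = numeric(), value = NA_real_, yBar = 1L)
  mp3 <- solveMaster(list(fc, push), branchState(0L, r = 2), K = 1,
                     zCap = 10)
  expect_equal(mp3$yBar, 0L)
  # an empty branched region reports infeasible
  empty <- branchState(c(0L, 0L), r = 1,
                       reverse = list(list(y = c(0L, 0L), rhs = 1)))
  expect_equal(solveMaster(list(), empty, K = 1, zCap = 10)$status,
               "infeasible")
})

test_that("the slave produces tight optimality cuts and exact feasibility
           cuts on toy5", {
  cand <- toy5Candidates()
  milp <- buildSingleLevelMILP(toy5, cand, "PRD", K = 2, growthFloor = 1)
  core <- corePoint(2, K = 2)
  s1 <- solveSlave(milp, c(1L, 0L), core)
  expect_equal(s1$kind, "optimality")
  expect_equal(s1$value, 1, tolerance = 1e-6)
  # the cut is tight at its generating design
  expect_equal(cutValueAt(s1$cut, c(1, 0)), 1, tolerance = 1e-5)
  # {R1, R3} kills growth: feasibility cut excluding exactly that design
  s2 <- solveSlave(milp, c(1L, 1L), core)
  expect_equal(s2$kind, "feasibility")
  expect_lt(cutValueAt(s2$cut, c(1, 1)), -1e-9)
  for (y in list(c(0, 0), c(1, 0), c(0, 1)))
    expect_gte(cutValueAt(s2$cut, y), -1e-9)
  # perturbed and unperturbed slave values agree to 1e-5
  s3 <- solveSlave(milp, c(1L, 0L), list(yHat = core$yHat, mu = 0))
  expect_equal(s1$value, s3$value, tolerance = 1e-5)
})

test_that("optimality cuts over-estimate the true value at every feasible
           design (cut validity)", {
  for (fx in fixtureGrid(c(1, 3, 5))) {
    bf <- bruteForceInterdiction(fx$model, fx$cand, fx$K, "PRD", fx$floor)
    res <- runHBA(fx$model, fx$cand, "PRD",
                  hbaConfig(K = fx$K, growthFloor = fx$floor, iterMax = 300))
    designs <- enumerateDesigns(length(fx$cand), fx$K)
    for (y in designs) {
      key <- paste(fx$cand@indices[y == 1], collapse = "+")
      key <- if (nzchar(key)) key else "(none)"
      truth <- bf$values[key]            # NA when the design is infeasible
      for (ct in res$cuts) {
        if (ct@kind == "optimality") {
          if (!is.na(truth))
            expect_gte(cutValueAt(ct, y), truth - 1e-5)
        } else {
          # feasibility cuts exclude exactly the infeasible designs
          if (!is.na(truth))
            expect_gte(cutValueAt(ct, y), -1e-6)
        }
      }
      if (is.na(truth)) {
        # every infeasible design is excluded by at least one feasibility cut
        # OR was simply never visited; when visited, its cut must cut it off
        viol <- any(vapply(res$cuts, function(ct)
          ct@kind == "feasibility" && identical(ct@yBar, as.integer(y)),
          logical(1)))
        if (viol) {
          excluded <- any(vapply(res$cuts, function(ct)
            ct@kind == "feasibility" && cutValueAt(ct, y) < -1e-9,
            logical(1)))
          expect_true(excluded)
        }
      }
    }
  }
})

test_that("Pareto cuts are never strictly dominated by the unperturbed cut", {
  cand <- toy5Candidates()
  milp <- buildSingleLevelMILP(toy5, cand, "PRD", K = 1, growthFloor = 1)
  core <- corePoint(2, K = 1)
  set.seed(3)
  for (yBar in list(c(0L, 0L), c(1L, 0L), c(0L, 1L))) {
    pareto <- solveSlave(milp, yBar, core)$cut
    plain <- solveSlave(milp, yBar, list(yHat = core$yHat, mu = 0))$cut
    ys <- replicate(100, rbinom(2, 1, 0.5), simplify = FALSE)
    ys <- Filter(function(y) sum(y) <= 1, ys)
    pv <- vapply(ys, function(y) cutValueAt(pareto, y), numeric(1))
    qv <- vapply(ys, function(y) cutValueAt(plain, y), numeric(1))
    dominated <- all(qv <= pv + 1e-9) && any(qv < pv - 1e-7)
    expect_false(dominated)
  }
})

test_that("HBA matches the brute-force oracle on toy5 and keeps its bounds
           monotone", {
  cand <- toy5Candidates()
  res <- runHBA(toy5, cand, "PRD", hbaConfig(K = 1, growthFloor = 1))
  expect_equal(res$best@valueGuaranteed, 1, tolerance = 1e-6)
  expect_equal(res$best@knockoutIds, "R1")
  expect_equal(res$status, "closed")
  expect_lte(res$zBar - res$zLow, 1e-4)
  expect_true(all(diff(res$trace$zBar) <= 1e-9))
  expect_true(all(diff(res$trace$zLow) >= -1e-9))
  expect_true(all(res$trace$zLow <= res$trace$zBar + 1e-6))
})

test_that("HBA reaches the brute-force optimum across random fixtures and
           its pool re-evaluates exactly", {
  for (fx in fixtureGrid(7:12)) {
    bf <- bruteForceInterdiction(fx$model, fx$cand, fx$K, "PRD", fx$floor)
    res <- runHBA(fx$model, fx$cand, "PRD",
                  hbaConfig(K = fx$K, growthFloor = fx$floor, iterMax = 300))
    expect_equal(res$best@valueGuaranteed, bf$bestValue, tolerance = 1e-5)
    expect_equal(res$status, "closed")
    expect_true(all(diff(res$trace$zBar) <= 1e-9))
    expect_true(all(diff(res$trace$zLow) >= -1e-9))
    # pool: no duplicates, stored values match the follower oracle
    keys <- vapply(res$pool, function(r)
      paste(sort(knockedReactions(r)), collapse = "+"), "")
    expect_false(anyDuplicated(keys) > 0)
    for (rec in res$pool) {
      re <- followerMinProduction(fx$model, "PRD", rec@design, fx$floor)
      expect_equal(rec@valueGuaranteed, re@objectiveValue, tolerance = 1e-6)
    }
  }
})
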