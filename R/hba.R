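#' @include milp.R
NULL

#' Hamming distance between binary vectors
#'
#' `sum_{y'_j = 0} y_j + sum_{y'_j = 1} (1 - y_j)`: the number of
#' coordinates in which the two designs differ.
#'
#' @param y,yPrime equal-length binary vectors.
#' @return integer count.
#' @export
hammingDistance <- function(y, yPrime) {
  if (length(y) != length(yPrime))
    stop("hammingDistance: length mismatch")
  sum(y[yPrime == 0]) + sum(1 - y[yPrime == 1])
}

#' Construct a core point
#'
#' A fractional point in the relative interior of the convex hull of the
#' feasible designs, used to steer Pareto-optimal cut generation.  The
#' default start is `min(0.5, K / (nCandidates + 1))` per coordinate,
#' which is interior (`0 < yHat_j < 1`, `sum(yHat) < K`) whenever
#' `K >= 1`.
#'
#' @param nCandidates number of candidate reactions.
#' @param K knockout budget.
#' @param mu perturbation weight for the Pareto slave (default 1e-8).
#' @return `list(yHat, mu)`
#' @export
corePoint <- function(nCandidates, K, mu = 1e-8) {
  stopifnot(K >= 1)
  list(yHat = rep(min(0.5, K / (nCandidates + 1)), nCandidates), mu = mu)
}

#' Update the core point with a new feasible design
#'
#' Component-wise averaging `yHat <- 0.5 (yHat + yBar)`; preserves
#' interiority when the start is interior.
#'
#' @param core a core point (`list(yHat, mu)`).
#' @param yBar binary feasible design.
#' @return the updated core point.
#' @export
updateCorePoint <- function(core, yBar) {
  stopifnot(length(core$yHat) == length(yBar))
  core$yHat <- 0.5 * (core$yHat + yBar)
  core
}

#' Master-problem early-termination gap schedule
#'
#' `1 + 300 / (sqrt(iter) + 1)`, interpreted as an absolute gap on the
#' master objective (flux units): early iterations only need a roughly
#' feasible master solution to produce useful cuts, later iterations are
#' solved nearly to optimality (the gap decreases towards 1).
#'
#' @param iter iteration counter (>= 0).
#' @return numeric gap.
#' @examples
#' mipGap(0)    # 301
#' mipGap(4)    # 101
#' @export
mipGap <- function(iter) {
  stopifnot(iter >= 0)
  1 + 300 / (sqrt(iter) + 1)
}

#' Construct a local-branching state
#'
#' @param yPrime binary incumbent reference design.
#' @param r branching radius (>= 1); the master is restricted to the
#'   Hamming ball `Delta_H(y, yPrime) <= r - 1` while the interior is
#'   active.
#' @param interiorActive logical.
#' @param reverse list of accumulated reverse inequalities, each
#'   `list(y, rhs)` meaning `Delta_H(y(.), y) >= rhs`.
#' @return `list` branch state.
#' @export
branchState <- function(yPrime, r = 3L, interiorActive = TRUE,
                        reverse = list()) {
  stopifnot(r >= 1)
  list(yPrime = as.integer(yPrime), r = as.integer(r),
       interiorActive = isTRUE(interiorActive), reverse = reverse)
}

# Hamming-distance inequality a'y {<=,>=} rhs - n1 in MP row form
.hammingRow <- function(yRef) {
  list(a = ifelse(yRef == 0, 1, -1), n1 = sum(yRef == 1))
}

#' Solve the Benders master problem
#'
#' Maximises the surrogate `z` over binary designs subject to the knockout
#' budget, all accumulated optimality cuts `z <= const + coef' y`,
#' feasibility cuts `const + coef' y >= 0`, the active local-branching
#' ball `Delta_H(y, y') <= r - 1`, any reverse inequalities, and
#' `0 <= z <= zCap`.  May stop at the supplied absolute gap.
#'
#' @param cuts list of [BendersCut-class].
#' @param branch a [branchState()] list.
#' @param K knockout budget.
#' @param zCap upper cap on `z` (initialise with the theoretical maximum
#'   production).
#' @param gap absolute early-termination gap on the master objective.
#' @return `list(status, yBar, zAtY, bound)`: the incumbent design, its
#'   surrogate value, and the master's dual (upper) bound; `status =
#'   "infeasible"` when the branched region is empty.
#' @export
solveMaster <- function(cuts, branch, K, zCap, gap = 0) {
  nc <- length(branch$yPrime)
  nv <- nc + 1L                       # y then z
  obj <- c(numeric(nc), 1)
  rows <- list(); clb <- c(); cub <- c()
  addRow <- function(a, lo, hi) {
    rows[[length(rows) + 1L]] <<- a
    clb <<- c(clb, lo); cub <<- c(cub, hi)
  }
  addRow(c(rep(1, nc), 0), -Inf, K)
  for (ct in cuts) {
    if (ct@kind == "optimality") {
      # z - coef'y <= const
      addRow(c(-ct@coefficients, 1), -Inf, ct@constant)
    } else {
      # const + coef'y >= 0
      addRow(c(ct@coefficients, 0), -ct@constant, Inf)
    }
  }
  if (branch$interiorActive) {
    h <- .hammingRow(branch$yPrime)
    addRow(c(h$a, 0), -Inf, branch$r - 1 - h$n1)
  }
  for (rv in branch$reverse) {
    h <- .hammingRow(rv$y)
    addRow(c(h$a, 0), rv$rhs - h$n1, Inf)
  }
  A <- do.call(rbind, rows)
  res <- milpSolveRaw(obj, "max", A = A, clb = clb, cub = cub,
                      integrality = c(rep(1L, nc), 0L),
                      lower = c(numeric(nc), 0),
                      upper = c(rep(1, nc), zCap),
                      relGap = min(1, gap / max(zCap, 1)))
  if (is.null(res$x))
    return(list(status = "infeasible", yBar = NULL, zAtY = NA_real_,
                bound = NA_real_))
  bound <- if (is.finite(res$bound)) min(res$bound, zCap) else zCap
  list(status = res$status,
       yBar = as.integer(round(res$x[seq_len(nc)])),
       zAtY = res$x[nv], bound = bound)
}

#' Solve the Benders slave for a fixed design
#'
#' Solves the continuous restriction of the single-level MILP at `y =
#' yBar` with the Pareto-perturbed right-hand side
#' `(b - B yBar) + mu (b - B yHat)` and reads the optimal dual vector: a
#' bounded solve yields an optimality cut from the dual extreme point
#' (with the perturbation's contribution removed from the reported value);
#' an infeasible slave yields a feasibility cut from a dual extreme ray
#' recovered via the phase-1 LP.
#'
#' @param milp a [SingleLevelMILP-class].
#' @param yBar binary design over the MILP's candidates.
#' @param core a core point (`list(yHat, mu)`); pass `mu = 0` for a plain
#'   (non-Pareto) cut.
#' @param resolveUnperturbed re-solve at `mu = 0` to report the exact
#'   slave value (default FALSE; the removed-perturbation value is within
#'   `mu * ||b - B yHat||` of it).
#' @return `list(kind, value, cut, x)`: `kind` is `"optimality"` or
#'   `"feasibility"`; `cut` is a [BendersCut-class]; `x` the continuous
#'   solution (optimality only).
#' @export
solveSlave <- function(milp, yBar, core, resolveUnperturbed = FALSE) {
  nc <- length(milp@candidates)
  stopifnot(length(yBar) == nc)
  rhs0 <- milp@b - as.numeric(milp@B %*% yBar)
  rhs <- rhs0 + core$mu * (milp@b - as.numeric(milp@B %*% core$yHat))
  res <- lpSolveRaw(milp@cbar, "max",
                    Aeq = milp@Seq, beq = numeric(nrow(milp@Seq)),
                    Aub = milp@A, bub = rhs,
                    lower = milp@lowerX, upper = milp@upperX)
  if (res$status == "optimal") {
    pi <- pmax(res$dualsUb, 0)     # >= 0 up to solver roundoff
    const <- sum(milp@b * pi)
    coef <- -as.numeric(Matrix::t(milp@B) %*% pi)
    value <- sum(rhs0 * pi)        # perturbation contribution removed
    if (resolveUnperturbed) {
      res0 <- lpSolveRaw(milp@cbar, "max",
                         Aeq = milp@Seq, beq = numeric(nrow(milp@Seq)),
                         Aub = milp@A, bub = rhs0,
                         lower = milp@lowerX, upper = milp@upperX)
      if (res0$status == "optimal") value <- res0$objective
    }
    cut <- new("BendersCut", kind = "optimality", constant = const,
               coefficients = coef, pi = pi, value = value,
               yBar = as.integer(yBar))
    return(list(kind = "optimality", value = value, cut = cut, x = res$x))
  }
  if (res$status != "infeasible")
    stop("slave solve failed with status ", res$status,
         "; the reformulated model should never be unbounded")
  fk <- farkasRay(Aeq = milp@Seq, beq = numeric(nrow(milp@Seq)),
                  Aub = milp@A, bub = rhs,
                  lower = milp@lowerX, upper = milp@upperX)
  if (fk$feasible)
    stop("slave reported infeasible but phase-1 found a feasible point")
  pi <- pmax(fk$rayUb, 0)
  cut <- new("BendersCut", kind = "feasibility",
             constant = sum(milp@b * pi),
             coefficients = -as.numeric(Matrix::t(milp@B) %*% pi),
             pi = pi, value = NA_real_, yBar = as.integer(yBar))
  list(kind = "feasibility", value = NA_real_, cut = cut, x = NULL)
}

#' Evaluate a Benders cut's affine form at a design
#' @param cut a [BendersCut-class].
#' @param y binary design.
#' @return `constant + coefficients' y`.
#' @export
cutValueAt <- function(cut, y) cut@constant + sum(cut@coefficients * y)

#' Hybrid-Benders run configuration
#'
#' @param K knockout budget.
#' @param minGrowthFraction growth floor as a fraction of wild-type
#'   maximum growth (default 0.1); overridden by `growthFloor`.
#' @param growthFloor absolute growth floor (1/h) or `NULL`.
#' @param thresholdFraction pool admission threshold as a fraction of the
#'   theoretical maximum production (default 0: keep every feasible
#'   design found).
#' @param mu Pareto perturbation weight (default 1e-8).
#' @param mRange penalty interval (default `c(90, 110)`).
#' @param penaltySeed seed for the penalty draw (default 2020).
#' @param r0 initial local-branching radius (default 3).
#' @param iterMax iteration cap (default 10000).
#' @param timeLimit wall-clock budget in seconds (default 3600).
#' @param tolClosure bound-closure tolerance (default 1e-4).
#' @param resolveUnperturbed see [solveSlave()].
#' @param verbose print one line per iteration.
#' @return a named list.
#' @export
hbaConfig <- function(K = 5, minGrowthFraction = 0.1, growthFloor = NULL,
                      thresholdFraction = 0, mu = 1e-8,
                      mRange = c(90, 110), penaltySeed = 2020,
                      r0 = 3, iterMax = 10000, timeLimit = 3600,
                      tolClosure = 1e-4, resolveUnperturbed = FALSE,
                      verbose = FALSE) {
  list(K = K, minGrowthFraction = minGrowthFraction,
       growthFloor = growthFloor, thresholdFraction = thresholdFraction,
       mu = mu, mRange = mRange, penaltySeed = penaltySeed, r0 = r0,
       iterMax = iterMax, timeLimit = timeLimit, tolClosure = tolClosure,
       resolveUnperturbed = resolveUnperturbed, verbose = verbose)
}

#' Run the hybrid Benders algorithm
#'
#' The master/slave loop with Pareto-optimal cuts, local branching on
#' Hamming distance, the early-termination gap schedule and an in-search
#' solution pool.  Each iteration solves the master inside the current
#' branching region at gap [mipGap()]; a feasible master design is
#' evaluated by the Pareto slave, whose cut is added and whose value
#' updates the incumbent and the pool; an infeasible master widens the
#' branching radius; the branch is reversed when the master bound inside
#' it falls to the incumbent value.  The run stops on bound closure
#' (`zBar - zLow <= tolClosure`), the iteration cap, or the wall-clock
#' budget.
#'
#' @param model a [MetabolicModel-class] whose wild type grows at least at
#'   the floor.
#' @param candidates a [CandidateSet-class].
#' @param target target reaction position or id.
#' @param config a [hbaConfig()] list.
#' @return `list(best, pool, trace, cuts, tmp, growthFloor, zBar, zLow,
#'   status)`:
#'   `best` is the [SolutionRecord-class] with the highest guaranteed
#'   minimum production, `pool` the deduplicated record list (value
#'   descending, then lexicographic design), and `trace` a per-iteration
#'   data frame (`iter, zBar, zLow, kind, r, poolSize, elapsed`).
#' @examples
#' \donttest{
#' toy <- makeToyNetwork("toy5")
#' cand <- selectCandidates(toy, "PRD", growthFloor = 1,
#'                          requireGeneRule = FALSE)
#' res <- runHBA(toy, cand, "PRD", hbaConfig(K = 1, growthFloor = 1))
#' res$best
#' }
#' @export
runHBA <- function(model, candidates, target, config = hbaConfig()) {
  t0 <- Sys.time()
  elapsed <- function() as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!length(candidates@indices)) stop("empty candidate set")
  wt <- solveFBA(model)
  if (wt@status != "optimal") stop("wild-type model is ", wt@status)
  floor <- if (!is.null(config$growthFloor)) config$growthFloor
           else config$minGrowthFraction * wt@objectiveValue
  if (wt@objectiveValue < floor)
    stop("wild-type growth is below the growth floor")
  tIdx <- .rxnIndex(model, target)
  tmp <- theoreticalMaxProduction(model, tIdx)
  nc <- length(candidates@indices)
  K <- as.integer(config$K)
  penalties <- samplePenalties(nc, seed = config$penaltySeed,
                               low = config$mRange[1], high = config$mRange[2])
  milp <- buildSingleLevelMILP(model, candidates, tIdx, K,
                               penalties = penalties, growthFloor = floor)
  core <- corePoint(nc, max(K, 1L), mu = config$mu)
  branch <- branchState(rep(0L, nc), r = config$r0, interiorActive = TRUE)
  cuts <- list()
  visited <- new.env(parent = emptyenv())
  poolDesigns <- list(); poolValues <- numeric()
  zBar <- tmp; zLow <- -Inf
  trace <- list()
  status <- "iteration_cap"
  lastKey <- ""; stall <- 0L
  iter <- 0L
  while (iter < config$iterMax) {
    iter <- iter + 1L
    if (elapsed() > config$timeLimit) { status <- "time_limit"; break }
    gap <- mipGap(iter - 1L)
    mp <- solveMaster(cuts, branch, K, zCap = tmp, gap = gap)
    kind <- "none"
    if (mp$status == "infeasible") {
      if (branch$interiorActive && branch$r - 1 < nc) {
        # explored ball is empty: exclude it and grow the radius by one,
        # so the next region is exactly the unexplored shell
        branch$reverse <- c(branch$reverse,
                            list(list(y = branch$yPrime, rhs = branch$r)))
        branch$r <- branch$r + 1L
        kind <- "widen"
      } else {
        # no feasible design left anywhere
        zBar <- max(zLow, 0)
        status <- if (is.finite(zLow)) "closed" else "infeasible"
        kind <- "exhausted"
        trace[[length(trace) + 1L]] <- data.frame(
          iter = iter, zBar = zBar, zLow = zLow, kind = kind,
          r = branch$r, poolSize = length(poolDesigns), elapsed = elapsed())
        break
      }
    } else {
      yBar <- mp$yBar
      key <- paste(yBar, collapse = "")
      revisit <- !is.null(visited[[key]])
      if (revisit) {
        s <- visited[[key]]
        kind <- "revisit"
        stall <- if (identical(key, lastKey)) stall + 1L else 0L
      } else {
        sl <- solveSlave(milp, yBar, core,
                         resolveUnperturbed = config$resolveUnperturbed)
        cuts <- c(cuts, list(sl$cut))
        kind <- sl$kind
        if (sl$kind == "optimality") {
          s <- sl$value
          core <- updateCorePoint(core, yBar)
          if (s >= config$thresholdFraction * tmp - 1e-12) {
            poolDesigns <- c(poolDesigns, list(yBar))
            poolValues <- c(poolValues, s)
          }
        } else {
          s <- NA_real_              # design cannot sustain the floor
        }
        visited[[key]] <- if (is.na(s)) -Inf else s
        stall <- 0L
      }
      lastKey <- key
      sVal <- if (is.null(visited[[key]])) -Inf else visited[[key]]
      if (is.finite(sVal)) zLow <- max(zLow, sVal)
      if (!branch$interiorActive)
        zBar <- min(zBar, max(mp$bound, zLow))
      if (branch$interiorActive &&
          (mp$bound <= zLow + 1e-9 || stall >= 3L)) {
        # neighbourhood certified (or stalled): reverse the branch
        branch$reverse <- c(branch$reverse,
                            list(list(y = branch$yPrime, rhs = branch$r)))
        branch$interiorActive <- FALSE
        kind <- paste0(kind, "+reverse")
        stall <- 0L
      } else if (is.finite(sVal) && mp$zAtY <= sVal + 1e-9 &&
                 !identical(yBar, branch$yPrime)) {
        # master value at yBar no better than its slave value:
        # recentre the branch on the new incumbent
        branch$yPrime <- yBar
        branch$r <- as.integer(config$r0)
        branch$interiorActive <- TRUE
        kind <- paste0(kind, "+recentre")
      } else if (!branch$interiorActive && stall >= 3L) {
        status <- "stalled"
        kind <- paste0(kind, "+stall")
      }
    }
    trace[[length(trace) + 1L]] <- data.frame(
      iter = iter, zBar = zBar, zLow = zLow, kind = kind, r = branch$r,
      poolSize = length(poolDesigns), elapsed = elapsed())
    if (config$verbose)
      message(sprintf("iter %4d  zBar %10.4f  zLow %10.4f  %-22s r=%d pool=%d",
                      iter, zBar, zLow, kind, branch$r, length(poolDesigns)))
    if (status == "stalled") break
    if (is.finite(zLow) && zBar - zLow <= config$tolClosure) {
      status <- "closed"; break
    }
  }
  trace <- do.call(rbind, trace)
  if (!length(poolDesigns))
    stop("no feasible design entered the pool; lower thresholdFraction ",
         "or relax the growth floor")
  # deduplicate, order by value descending then lexicographic design
  keys <- vapply(poolDesigns, paste, "", collapse = "")
  keep <- !duplicated(keys)
  poolDesigns <- poolDesigns[keep]; poolValues <- poolValues[keep]
  ord <- order(-poolValues, vapply(poolDesigns, paste, "", collapse = ""))
  poolDesigns <- poolDesigns[ord]; poolValues <- poolValues[ord]
  pool <- mapply(function(y, val) {
    dv <- new("DesignVector", y = as.integer(y),
              candidates = milp@candidates, K = K)
    rec <- evaluateRecord(model, dv, tIdx, tmp = tmp)
    rec@valueGuaranteed <- val
    rec
  }, poolDesigns, poolValues, SIMPLIFY = FALSE)
  list(best = pool[[1]], pool = pool, trace = trace, cuts = cuts,
       tmp = tmp, growthFloor = floor, zBar = zBar, zLow = zLow,
       status = status)
}
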