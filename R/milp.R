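#' @include fba.R
NULL

#' Sample Lagrange penalty multipliers
#'
#' Independent uniform draws in `[low, high]`, one per candidate reaction,
#' reproducible for a given seed.  The penalties weight the `u_j y_j` terms
#' of the Lagrangian follower objective; values around 100 are large enough
#' to force knocked-out fluxes to zero on typical networks while keeping
#' the LP numerically benign (unlike disjunctive big-M constraints).
#'
#' @param nCandidates number of candidates.
#' @param seed integer seed (default 2020).
#' @param low,high interval endpoints, `low < high` (or equal for a
#'   constant vector).
#' @return numeric penalty vector with attribute `"seed"`.
#' @export
samplePenalties <- function(nCandidates, seed = 2020, low = 90, high = 110) {
  stopifnot(low <= high)
  M <- withSeed(seed, stats::runif(nCandidates, low, high))
  attr(M, "seed") <- as.integer(seed)
  M
}

#' Build the Lagrangian follower LP
#'
#' The inner (cell's) problem with knockout constraints moved into the
#' objective: `min c_P' v + sum_j M_j y_j u_j` over `S v = 0`,
#' `u_j >= v_j`, `u_j >= -v_j`, `lb <= v <= ub`, `0 <= u <= U` with
#' `U_j = max(|lb_j|, |ub_j|)`, and `v_biomass >= growthFloor`.  For
#' sufficiently large penalties its optimum equals the direct inner LP
#' ([followerMinProduction()]) on the same design.
#'
#' @param model a [MetabolicModel-class].
#' @param target target reaction position or id.
#' @param penalties numeric penalties over the design's candidates
#'   (see [samplePenalties()]).
#' @param design a [DesignVector-class].
#' @param growthFloor minimum biomass flux (1/h).
#' @return an object of class `"FollowerLP"` (list of LP blocks), to be
#'   solved with [solveFollowerLP()].
#' @export
buildFollowerLP <- function(model, target, penalties, design,
                            growthFloor = 0) {
  stopifnot(length(penalties) == length(design@candidates))
  n <- nReactions(model)
  m <- nMetabolites(model)
  tIdx <- .rxnIndex(model, target)
  U <- pmax(abs(model@lb), abs(model@ub))
  My <- numeric(n)
  My[design@candidates] <- penalties * design@y
  obj <- c(numeric(n), My)
  obj[tIdx] <- 1
  In <- Matrix::Diagonal(n)
  Aub <- rbind(cbind(In, -In),     # v - u <= 0
               cbind(-In, -In))    # -v - u <= 0
  bub <- numeric(2 * n)
  grow <- Matrix::sparseMatrix(i = 1, j = model@biomassIndex, x = -1,
                               dims = c(1, 2 * n))
  Aub <- rbind(Aub, grow)
  bub <- c(bub, -growthFloor)
  structure(list(obj = obj,
                 Aeq = cbind(model@S, Matrix::Matrix(0, m, n, sparse = TRUE)),
                 beq = numeric(m),
                 Aub = Aub, bub = bub,
                 lower = c(model@lb, numeric(n)),
                 upper = c(model@ub, U),
                 n = n, U = U, targetIndex = tIdx,
                 design = design, growthFloor = growthFloor),
            class = "FollowerLP")
}

#' Solve a follower LP
#'
#' @param flp a `"FollowerLP"` from [buildFollowerLP()].
#' @return `list(status, value, v, u)`; `value` is the penalised optimum
#'   (equal to the plain inner minimum whenever the penalty suffices).
#' @export
solveFollowerLP <- function(flp) {
  res <- lpSolveRaw(flp$obj, "min", Aeq = flp$Aeq, beq = flp$beq,
                    Aub = flp$Aub, bub = flp$bub,
                    lower = flp$lower, upper = flp$upper)
  if (res$status != "optimal")
    return(list(status = res$status, value = NA_real_, v = NULL, u = NULL))
  list(status = "optimal", value = res$objective,
       v = res$x[seq_len(flp$n)], u = res$x[flp$n + seq_len(flp$n)])
}

# x column layout of the single-level MILP
.milpBlocks <- function(n, m) {
  at <- 0L
  blk <- function(len) { r <- at + seq_len(len); at <<- at + len; r }
  list(v = blk(n), u = blk(n), lambda = blk(m),
       alpha = blk(n), beta = blk(n), gamma = blk(n),
       rho = blk(n), sigma = blk(n), delta = blk(1L))
}

#' Build the duality-reformulated single-level MILP
#'
#' Reformulates the max-min interdiction problem to a single-level MILP:
#' maximise the target flux `c_P' v` over designs `y` (binary, at most `K`
#' knockouts) and a continuous stack `x` containing the follower primal
#' `(v, u)` and the follower dual `(lambda, alpha, beta, gamma, rho, sigma,
#' delta)`, subject to
#'
#' * follower primal feasibility (steady state, magnitude couplings
#'   `u >= |v|`, flux bounds, magnitude caps `u <= U`, growth floor),
#' * follower dual feasibility, whose `u`-columns are relaxed by
#'   `M_j y_j` (the `-diag(M)` block of `B`),
#' * the strong-duality equality linking the primal and dual objectives,
#' * coupling rows `u_j + U_j y_j <= U_j` (the `diag(U)` block of `B`),
#'   which force `u_j = v_j = 0` for knocked-out reactions — and thereby
#'   cancel the bilinear `M_j y_j u_j` term of the strong-duality row,
#' * the knockout budget `sum(y) <= K`.
#'
#' At any optimum the `v`-component's target flux equals the inner minimum
#' for the chosen `y`.  Equality rows other than steady state are encoded
#' as paired inequalities so that every Benders slave row sits in
#' `A x + B y <= b`.
#'
#' @param model a [MetabolicModel-class].
#' @param candidates a [CandidateSet-class] (must not contain the biomass
#'   or target reaction).
#' @param target target reaction position or id.
#' @param K knockout budget (>= 0).
#' @param penalties numeric penalties over candidates.
#' @param growthFloor minimum biomass flux (1/h).
#' @return a [SingleLevelMILP-class]
#' @export
buildSingleLevelMILP <- function(model, candidates, target, K,
                                 penalties = samplePenalties(length(candidates)),
                                 growthFloor = 0) {
  stopifnot(K >= 0, length(candidates) > 0,
            length(penalties) == length(candidates))
  n <- nReactions(model)
  m <- nMetabolites(model)
  tIdx <- .rxnIndex(model, target)
  cand <- candidates@indices
  if (model@biomassIndex %in% cand || tIdx %in% cand)
    stop("candidate set must exclude the biomass and target reactions")
  U <- pmax(abs(model@lb), abs(model@ub))
  blocks <- .milpBlocks(n, m)
  nx <- blocks$delta[length(blocks$delta)]
  nc <- length(cand)
  cP <- numeric(n); cP[tIdx] <- 1
  eBio <- numeric(n); eBio[model@biomassIndex] <- 1

  sp <- function(i, j, x, nrow) Matrix::sparseMatrix(i = i, j = j, x = x,
                                                     dims = c(nrow, nx))
  In <- seq_len(n)
  rows <- list(); Brows <- list(); bvec <- list(); rowTag <- list()
  addRows <- function(A, B, b, tag) {
    rows[[length(rows) + 1L]] <<- A
    Brows[[length(Brows) + 1L]] <<- B
    bvec[[length(bvec) + 1L]] <<- b
    rowTag[[length(rowTag) + 1L]] <<- rep(tag, length(b))
  }
  zeroB <- function(k) Matrix::Matrix(0, k, nc, sparse = TRUE)
  # r1: v - u <= 0
  addRows(sp(c(In, In), c(blocks$v, blocks$u), c(rep(1, n), rep(-1, n)), n),
          zeroB(n), numeric(n), "uAbs+")
  # r2: -v - u <= 0
  addRows(sp(c(In, In), c(blocks$v, blocks$u), c(rep(-1, n), rep(-1, n)), n),
          zeroB(n), numeric(n), "uAbs-")
  # r3: u <= U  (dualised by gamma)
  addRows(sp(In, blocks$u, rep(1, n), n), zeroB(n), U, "uCap")
  # r4: v <= ub (rho)
  addRows(sp(In, blocks$v, rep(1, n), n), zeroB(n), model@ub, "vUpper")
  # r5: -v <= -lb (sigma)
  addRows(sp(In, blocks$v, rep(-1, n), n), zeroB(n), -model@lb, "vLower")
  # r6: -v_bio <= -growthFloor (delta)
  addRows(sp(1, blocks$v[model@biomassIndex], -1, 1), zeroB(1),
          -growthFloor, "growth")
  # r7: u_j + U_j y_j <= U_j  (coupling; diag(U) block of B)
  addRows(sp(In, blocks$u, rep(1, n), n),
          Matrix::sparseMatrix(i = cand, j = seq_len(nc), x = U[cand],
                               dims = c(n, nc)),
          U, "coupling")
  # r8: alpha + beta - gamma - M_j y_j <= 0  (dual capacity; -diag(M) block)
  addRows(sp(c(In, In, In), c(blocks$alpha, blocks$beta, blocks$gamma),
             c(rep(1, n), rep(1, n), rep(-1, n)), n),
          Matrix::sparseMatrix(i = cand, j = seq_len(nc), x = -penalties,
                               dims = c(n, nc)),
          numeric(n), "dualCap")
  # r9: dual stationarity for v:  S'lambda + alpha - beta + rho - sigma
  #     - delta * e_bio = -c_P   (paired inequalities)
  St <- Matrix::t(model@S)
  statA <- sp(c(In, In, In, In), c(blocks$alpha, blocks$beta, blocks$rho,
                                   blocks$sigma),
              c(rep(1, n), rep(-1, n), rep(1, n), rep(-1, n)), n)
  statA[, blocks$lambda] <- St
  statA[, blocks$delta] <- -eBio
  addRows(statA, zeroB(n), -cP, "stat+")
  addRows(-statA, zeroB(n), cP, "stat-")
  # r10: strong duality  c_P'v + U'gamma + ub'rho - lb'sigma - gf*delta = 0
  sd <- sp(c(rep(1, n), rep(1, n), rep(1, n), rep(1, n), 1),
           c(blocks$v, blocks$gamma, blocks$rho, blocks$sigma, blocks$delta),
           c(cP, U, model@ub, -model@lb, -growthFloor), 1)
  addRows(sd, zeroB(1), 0, "duality+")
  addRows(-sd, zeroB(1), 0, "duality-")

  A <- do.call(rbind, rows)
  B <- do.call(rbind, Brows)
  b <- unlist(bvec)
  tags <- unlist(rowTag)
  cbar <- numeric(nx); cbar[blocks$v[tIdx]] <- 1
  lowerX <- rep(0, nx); upperX <- rep(Inf, nx)
  lowerX[blocks$v] <- -Inf          # v bounded by rows r4/r5
  lowerX[blocks$lambda] <- -Inf     # lambda free
  Seq <- cbind(model@S, Matrix::Matrix(0, m, nx - n, sparse = TRUE))
  blocks$rowTags <- tags
  new("SingleLevelMILP",
      cbar = cbar,
      Seq = as(as(Seq, "generalMatrix"), "CsparseMatrix"),
      A = as(as(A, "generalMatrix"), "CsparseMatrix"),
      B = as(as(B, "generalMatrix"), "CsparseMatrix"),
      b = as.numeric(b),
      lowerX = lowerX, upperX = upperX, blocks = blocks,
      candidates = as.integer(cand), K = as.integer(K),
      penalties = as.numeric(penalties), U = U,
      targetIndex = as.integer(tIdx), growthFloor = as.numeric(growthFloor))
}

setMethod("show", "SingleLevelMILP", function(object) {
  cat("SingleLevelMILP:", length(object@cbar), "continuous variables,",
      length(object@candidates), "binary knockouts, K =", object@K, "\n")
  cat("  rows:", nrow(object@Seq), "equalities +", nrow(object@A),
      "inequalities\n")
})

#' Strong-duality residual at a MILP solution
#'
#' `|follower primal objective - follower dual objective|` evaluated on
#' the continuous stack `x`; at any clean optimum this is ~0.
#'
#' @param milp a [SingleLevelMILP-class].
#' @param x numeric continuous solution stack.
#' @return nonnegative scalar.
#' @export
strongDualityResidual <- function(milp, x) {
  bl <- milp@blocks
  n <- length(bl$v)
  cP <- numeric(n); cP[milp@targetIndex] <- 1
  # primal objective includes the (vanishing) penalty term M_j y_j u_j = 0
  primal <- sum(cP * x[bl$v])
  lbv <- -milp@b[which(bl$rowTags == "vLower")]
  ubv <- milp@b[which(bl$rowTags == "vUpper")]
  dual <- -sum(milp@U * x[bl$gamma]) - sum(ubv * x[bl$rho]) +
    sum(lbv * x[bl$sigma]) + milp@growthFloor * x[bl$delta]
  abs(primal - dual)
}

#' Solve the single-level MILP directly
#'
#' Hands the whole duality-reformulated MILP to the MILP engine — the
#' classic single-shot baseline against which the Benders decomposition is
#' compared.
#'
#' @param milp a [SingleLevelMILP-class].
#' @param timeLimit optional wall-clock limit in seconds.
#' @param relGap relative MIP gap (default 0).
#' @return `list(value, design, status, x, y)`; `design` is a
#'   [DesignVector-class].
#' @export
solveDirect <- function(milp, timeLimit = NULL, relGap = 0) {
  nx <- length(milp@cbar)
  nc <- length(milp@candidates)
  obj <- c(milp@cbar, numeric(nc))
  Aall <- rbind(
    cbind(milp@Seq, Matrix::Matrix(0, nrow(milp@Seq), nc, sparse = TRUE)),
    cbind(milp@A, milp@B),
    Matrix::sparseMatrix(i = rep(1, nc), j = nx + seq_len(nc), x = rep(1, nc),
                         dims = c(1, nx + nc)))
  clb <- c(numeric(nrow(milp@Seq)), rep(-Inf, nrow(milp@A)), -Inf)
  cub <- c(numeric(nrow(milp@Seq)), milp@b, milp@K)
  res <- milpSolveRaw(obj, "max", A = Aall, clb = clb, cub = cub,
                      integrality = c(rep(0L, nx), rep(1L, nc)),
                      lower = c(milp@lowerX, numeric(nc)),
                      upper = c(milp@upperX, rep(1, nc)),
                      relGap = relGap, timeLimit = timeLimit)
  if (is.null(res$x))
    return(list(value = NA_real_, design = NULL, status = res$status,
                x = NULL, y = NULL))
  y <- as.integer(round(res$x[nx + seq_len(nc)]))
  design <- new("DesignVector", y = y, candidates = milp@candidates,
                K = milp@K)
  list(value = res$objective, design = design, status = res$status,
       x = res$x[seq_len(nx)], y = y)
}

#' Exhaustive interdiction oracle
#'
#' Enumerates every knockout subset of size at most `K`, evaluates each
#' with [followerMinProduction()] and returns the best guaranteed minimum
#' production together with every argmax design.  Infeasible designs are
#' skipped.  Guarded to at most 5000 subsets.
#'
#' @param model a [MetabolicModel-class].
#' @param candidates a [CandidateSet-class].
#' @param K knockout budget.
#' @param target target reaction position or id.
#' @param growthFloor minimum biomass flux (1/h).
#' @param tieTol designs within `tieTol` of the best value are reported.
#' @return `list(bestValue, bestDesigns = list of DesignVector, values =
#'   named numeric over all feasible subsets)`
#' @export
bruteForceInterdiction <- function(model, candidates, K, target,
                                   growthFloor = 0, tieTol = 1e-6) {
  cand <- candidates@indices
  nSubsets <- sum(choose(length(cand), 0:min(K, length(cand))))
  if (nSubsets > 5000)
    stop("more than 5000 subsets to enumerate; use runHBA() instead")
  best <- -Inf
  designs <- list()
  values <- numeric(0)
  for (k in 0:min(K, length(cand))) {
    combs <- if (k == 0) list(integer()) else
      asplit(utils::combn(cand, k), 2)
    for (ko in combs) {
      dv <- designVector(as.integer(ko), cand, K = K)
      sol <- followerMinProduction(model, target, dv, growthFloor)
      if (sol@status != "optimal") next
      key <- paste(ko, collapse = "+")
      values[if (nzchar(key)) key else "(none)"] <- sol@objectiveValue
      if (sol@objectiveValue > best + tieTol) {
        best <- sol@objectiveValue
        designs <- list(dv)
      } else if (abs(sol@objectiveValue - best) <= tieTol) {
        designs <- c(designs, list(dv))
      }
    }
  }
  if (!length(designs)) stop("no feasible design at the given growth floor")
  list(bestValue = best, bestDesigns = designs, values = values)
}

#' Write the MILP in LP file format
#'
#' Emits the duality-reformulated MILP in the standard CPLEX-style LP text
#' format for inspection with external solvers.
#'
#' @param milp a [SingleLevelMILP-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMilpLp <- function(milp, path) {
  nx <- length(milp@cbar)
  nc <- length(milp@candidates)
  xn <- paste0("x", seq_len(nx))
  yn <- paste0("y", seq_len(nc))
  term <- function(coefs, names) {
    nz <- which(coefs != 0)
    if (!length(nz)) return("0 x1")
    paste(sprintf("%+.12g %s", coefs[nz], names[nz]), collapse = " ")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines("Maximize", con)
  writeLines(paste(" obj:", term(milp@cbar, xn)), con)
  writeLines("Subject To", con)
  Se <- as.matrix(milp@Seq); A <- as.matrix(milp@A); B <- as.matrix(milp@B)
  for (i in seq_len(nrow(Se)))
    writeLines(sprintf(" eq%d: %s = 0", i, term(Se[i, ], xn)), con)
  for (i in seq_len(nrow(A)))
    writeLines(sprintf(" le%d: %s %s <= %.12g", i, term(A[i, ], xn),
                       if (any(B[i, ] != 0)) term(B[i, ], yn) else "",
                       milp@b[i]), con)
  writeLines(sprintf(" bud: %s <= %d", term(rep(1, nc), yn), milp@K), con)
  writeLines("Bounds", con)
  for (j in seq_len(nx)) {
    lo <- milp@lowerX[j]; hi <- milp@upperX[j]
    writeLines(sprintf(" %s %s %s",
                       if (is.finite(lo)) sprintf("%.12g <=", lo) else "-inf <=",
                       xn[j],
                       if (is.finite(hi)) sprintf("<= %.12g", hi) else ""), con)
  }
  writeLines("Binary", con)
  writeLines(paste("", paste(yn, collapse = " ")), con)
  writeLines("End", con)
  invisible(path)
}
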