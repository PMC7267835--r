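# LP/MILP backend.
#
# Solver contract used throughout the package: given an objective sense,
# linear constraints (equalities and <= inequalities), variable bounds and an
# integrality mask, return status, primal values, LP duals in sensitivity
# convention (dObj/dRHS) and, on primal infeasibility, a Farkas certificate
# recovered from the phase-1 (elastic) LP.  The engine behind the contract is
# the HiGHS solver of scipy.optimize, reached through reticulate; any engine
# honouring the contract could be swapped in.

.pkgenv <- new.env(parent = emptyenv())

.scipyOpt <- function() {
  if (is.null(.pkgenv$scipy_optimize)) {
    if (Sys.getenv("RETICULATE_PYTHON") == "" &&
        is.null(getOption("reticulate.python"))) {
      py <- Sys.which("python3")
      if (py == "") py <- Sys.which("python")
      if (py != "") Sys.setenv(RETICULATE_PYTHON = py)
    }
    .pkgenv$scipy_optimize <- reticulate::import("scipy.optimize",
                                                 delay_load = FALSE)
  }
  .pkgenv$scipy_optimize
}

.lpStatus <- function(code) {
  switch(as.character(code),
         "0" = "optimal",
         "1" = "iteration_limit",
         "2" = "infeasible",
         "3" = "unbounded",
         "numerical")
}

.denseMat <- function(A) {
  if (is.null(A)) return(NULL)
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  A
}

#' @noRd
#' @keywords internal
lpSolveRaw <- function(obj, sense = c("min", "max"),
                       Aeq = NULL, beq = NULL,
                       Aub = NULL, bub = NULL,
                       lower = NULL, upper = NULL) {
  sense <- match.arg(sense)
  sp <- .scipyOpt()
  n <- length(obj)
  if (is.null(lower)) lower <- rep(-Inf, n)
  if (is.null(upper)) upper <- rep(Inf, n)
  sgn <- if (sense == "max") -1 else 1
  bounds <- cbind(lower, upper)
  args <- list(sgn * obj, bounds = bounds, method = "highs")
  if (!is.null(Aub)) {
    args$A_ub <- .denseMat(Aub)
    args$b_ub <- as.numeric(bub)
  }
  if (!is.null(Aeq)) {
    args$A_eq <- .denseMat(Aeq)
    args$b_eq <- as.numeric(beq)
  }
  res <- do.call(sp$linprog, args)
  status <- .lpStatus(res$status)
  out <- list(status = status, x = NULL, objective = NA_real_,
              dualsEq = NULL, dualsUb = NULL)
  if (status == "optimal") {
    out$x <- as.numeric(res$x)
    out$objective <- sgn * as.numeric(res$fun)
    # marginals are d(min objective)/d(rhs); convert to the requested sense
    if (!is.null(Aub)) out$dualsUb <- sgn * as.numeric(res$ineqlin$marginals)
    if (!is.null(Aeq)) out$dualsEq <- sgn * as.numeric(res$eqlin$marginals)
  }
  out
}

# Farkas certificate of infeasibility for {Aeq x = beq, Aub x <= bub,
# lower <= x <= upper}: solved as the elastic phase-1 LP
#   min sum(s)  s.t.  Aub x - s <= bub, Aeq x = beq, s >= 0.
# When the optimum t* is positive the system is infeasible and the phase-1
# duals give a ray (piUb >= 0, piEq) with  bub' piUb + beq' piEq = -t* < 0
# while (b - By)' pi >= 0 holds for every feasible right-hand side.
#' @noRd
#' @keywords internal
farkasRay <- function(Aeq = NULL, beq = NULL, Aub, bub,
                      lower = NULL, upper = NULL, tol = 1e-9) {
  Aub <- .denseMat(Aub)
  m <- nrow(Aub)
  n <- ncol(Aub)
  if (is.null(lower)) lower <- rep(-Inf, n)
  if (is.null(upper)) upper <- rep(Inf, n)
  objP <- c(rep(0, n), rep(1, m))
  AubP <- cbind(Aub, -diag(m))
  AeqP <- if (is.null(Aeq)) NULL else cbind(.denseMat(Aeq), matrix(0, nrow(Aeq), m))
  res <- lpSolveRaw(objP, "min",
                    Aeq = AeqP, beq = beq,
                    Aub = AubP, bub = bub,
                    lower = c(lower, rep(0, m)),
                    upper = c(upper, rep(Inf, m)))
  if (res$status != "optimal")
    stop("phase-1 LP did not solve cleanly (status ", res$status, ")")
  if (res$objective <= tol)
    return(list(feasible = TRUE, rayUb = NULL, rayEq = NULL,
                infeasibility = res$objective))
  # phase-1 is a min problem: marginals are d(t*)/d(rhs); the Farkas ray of
  # the original system is the negated inequality marginal (>= 0).
  list(feasible = FALSE,
       rayUb = -res$dualsUb,
       rayEq = if (is.null(Aeq)) NULL else -res$dualsEq,
       infeasibility = res$objective)
}

#' @noRd
#' @keywords internal
milpSolveRaw <- function(obj, sense = c("min", "max"),
                         A = NULL, clb = NULL, cub = NULL,
                         integrality = NULL,
                         lower = NULL, upper = NULL,
                         relGap = 0, timeLimit = NULL) {
  sense <- match.arg(sense)
  sp <- .scipyOpt()
  n <- length(obj)
  if (is.null(lower)) lower <- rep(-Inf, n)
  if (is.null(upper)) upper <- rep(Inf, n)
  if (is.null(integrality)) integrality <- rep(0L, n)
  sgn <- if (sense == "max") -1 else 1
  opts <- list(mip_rel_gap = as.numeric(relGap))
  if (!is.null(timeLimit)) opts$time_limit <- as.numeric(timeLimit)
  args <- list(sgn * obj,
               integrality = as.integer(integrality),
               bounds = sp$Bounds(as.numeric(lower), as.numeric(upper)),
               options = reticulate::dict(opts))
  if (!is.null(A)) {
    m <- nrow(A)
    if (is.null(clb)) clb <- rep(-Inf, m)
    if (is.null(cub)) cub <- rep(Inf, m)
    args$constraints <- sp$LinearConstraint(.denseMat(A),
                                            lb = as.numeric(clb),
                                            ub = as.numeric(cub))
  }
  res <- do.call(sp$milp, args)
  status <- switch(as.character(res$status),
                   "0" = "optimal",
                   "1" = "iteration_limit",
                   "2" = "infeasible",
                   "3" = "unbounded",
                   "4" = "numerical",
                   "timeout")
  out <- list(status = status, x = NULL, objective = NA_real_,
              bound = NA_real_)
  if (!is.null(res$x)) {
    out$x <- as.numeric(res$x)
    out$objective <- sgn * as.numeric(res$fun)
    if (status %in% c("iteration_limit", "timeout")) status <- "feasible"
    out$status <- if (status == "optimal") "optimal" else status
  }
  if (!is.null(res$mip_dual_bound) && length(res$mip_dual_bound))
    out$bound <- sgn * as.numeric(res$mip_dual_bound)
  out
}

# run a block with a private RNG stream, restoring the caller's stream
#' @noRd
#' @keywords internal
withSeed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
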