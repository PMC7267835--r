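#' @include MetabolicModel-methods.R solver.R
NULL

# package-wide numerical tolerances
.TOL_FEAS <- 1e-9   # LP feasibility
.TOL_ZERO <- 1e-6   # zero-flux / coupling tolerance

#' Flux balance analysis
#'
#' Solves the LP `opt c' v` subject to `S v = 0` and `lb <= v <= ub`, where
#' the objective selects a single reaction (by default the biomass
#' reaction).  Infeasibility and unboundedness are reported in the
#' solution's `status`, never raised as errors.
#'
#' @param model a [MetabolicModel-class].
#' @param objectiveIndex reaction position or id to optimise; defaults to
#'   the biomass reaction.
#' @param sense `"max"` or `"min"`.
#' @param extraBounds optional per-reaction overrides: a named list mapping
#'   reaction id (or a character position) to a `c(lb, ub)` pair.
#' @return a [FluxSolution-class]; for optimal solves, `duals` holds the
#'   per-metabolite dual values of the steady-state rows.
#' @examples
#' toy <- makeToyNetwork("toy5")
#' solveFBA(toy)@objectiveValue                    # 10
#' solveFBA(toy, "PRD", sense = "min")@objectiveValue  # 0
#' @export
solveFBA <- function(model, objectiveIndex = NULL, sense = c("max", "min"),
                     extraBounds = NULL) {
  sense <- match.arg(sense)
  j <- if (is.null(objectiveIndex)) model@biomassIndex
       else .rxnIndex(model, objectiveIndex)
  n <- nReactions(model)
  obj <- numeric(n); obj[j] <- 1
  lb <- model@lb; ub <- model@ub
  if (!is.null(extraBounds)) {
    for (nm in names(extraBounds)) {
      k <- .rxnIndex(model, nm)
      lb[k] <- extraBounds[[nm]][1]; ub[k] <- extraBounds[[nm]][2]
    }
  }
  res <- lpSolveRaw(obj, sense, Aeq = model@S, beq = numeric(nMetabolites(model)),
                    lower = lb, upper = ub)
  if (res$status == "optimal")
    new("FluxSolution", v = res$x, objectiveValue = res$objective,
        status = "optimal", duals = res$dualsEq)
  else
    new("FluxSolution", v = numeric(), objectiveValue = NA_real_,
        status = res$status, duals = numeric())
}

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status)
  if (object@status == "optimal")
    cat(sprintf(", objective %.6g", object@objectiveValue))
  cat("\n")
})

#' Theoretical maximum production (TMP)
#'
#' The FBA optimum when the objective is the target reaction flux itself;
#' the denominator of all "% TMP" reporting.  Computed without a growth
#' floor.
#'
#' @param model a [MetabolicModel-class].
#' @param target target reaction position or id.
#' @return scalar flux, mmol/gDW/h.
#' @export
theoreticalMaxProduction <- function(model, target) {
  sol <- solveFBA(model, target, "max")
  if (sol@status != "optimal")
    stop("model is ", sol@status, "; cannot compute theoretical maximum production")
  sol@objectiveValue
}

#' Follower (inner) problem: guaranteed minimum production of a design
#'
#' For a fixed knockout design, solves `min c_P' v` over `S v = 0`,
#' knocked-out reactions fixed to zero, flux bounds, and a minimum-growth
#' constraint `v_biomass >= growthFloor`.  This is the evaluation oracle
#' for any design: its optimum is the production rate the mutant cannot go
#' below while satisfying the growth requirement.
#'
#' @param model a [MetabolicModel-class].
#' @param target target reaction position or id.
#' @param design a [DesignVector-class] (or integer/character knockouts).
#' @param growthFloor minimum biomass flux (1/h), `>= 0`.
#' @return a [FluxSolution-class]; `status` is `"infeasible"` when the
#'   design cannot sustain the growth floor.
#' @export
followerMinProduction <- function(model, target, design = NULL,
                                  growthFloor = 0) {
  stopifnot(growthFloor >= 0)
  ko <- if (is.null(design)) model else applyKnockouts(model, design)
  tIdx <- .rxnIndex(model, target)
  n <- nReactions(ko)
  obj <- numeric(n); obj[tIdx] <- 1
  lb <- ko@lb; ub <- ko@ub
  bi <- ko@biomassIndex
  lb[bi] <- max(lb[bi], growthFloor)
  if (lb[bi] > ub[bi])
    return(new("FluxSolution", v = numeric(), objectiveValue = NA_real_,
               status = "infeasible", duals = numeric()))
  res <- lpSolveRaw(obj, "min", Aeq = ko@S, beq = numeric(nMetabolites(ko)),
                    lower = lb, upper = ub)
  if (res$status == "optimal")
    new("FluxSolution", v = res$x, objectiveValue = res$objective,
        status = "optimal", duals = res$dualsEq)
  else
    new("FluxSolution", v = numeric(), objectiveValue = NA_real_,
        status = res$status, duals = numeric())
}

#' Production envelope
#'
#' Minimum and maximum target flux while the biomass flux is fixed, by
#' equality, to each point of a grid spanning 0 to the knocked-out model's
#' maximum growth.  The coupling class is attached via [classifyCoupling()].
#'
#' @param model a [MetabolicModel-class].
#' @param target target reaction position or id.
#' @param design optional knockout design applied before the sweep.
#' @param nPoints number of grid points (>= 2).
#' @return an [EnvelopeCurve-class]
#' @examples
#' toy <- makeToyNetwork("toy5")
#' env <- productionEnvelope(toy, "PRD", designVector("R1", model = toy))
#' env@couplingClass   # "growth_coupled"
#' @export
productionEnvelope <- function(model, target, design = NULL, nPoints = 20) {
  stopifnot(nPoints >= 2)
  ko <- if (is.null(design)) model else applyKnockouts(model, design)
  tIdx <- .rxnIndex(model, target)
  gmax <- solveFBA(ko)
  if (gmax@status != "optimal")
    stop("design infeasible: empty production envelope")
  grid <- seq(0, gmax@objectiveValue, length.out = nPoints)
  bio <- ko@reactionIds[ko@biomassIndex]
  lo <- hi <- numeric(nPoints)
  for (k in seq_len(nPoints)) {
    fix <- list(c(grid[k], grid[k])); names(fix) <- bio
    mn <- solveFBA(ko, tIdx, "min", extraBounds = fix)
    mx <- solveFBA(ko, tIdx, "max", extraBounds = fix)
    if (mn@status != "optimal" || mx@status != "optimal")
      stop("envelope LP not optimal at biomass ", signif(grid[k], 6))
    lo[k] <- mn@objectiveValue; hi[k] <- mx@objectiveValue
  }
  curve <- new("EnvelopeCurve", biomassGrid = grid, minProduction = lo,
               maxProduction = hi, couplingClass = "none")
  curve@couplingClass <- classifyCoupling(curve)
  curve
}

#' Growth-coupling classification of an envelope
#'
#' `"strong"` iff the guaranteed minimum production at zero growth exceeds
#' `tol`; `"growth_coupled"` iff the minimum production at maximum growth
#' exceeds `tol` but the design is not strong; `"none"` otherwise.
#'
#' @param curve an [EnvelopeCurve-class].
#' @param tol flux tolerance, mmol/gDW/h.
#' @return one of `"none"`, `"growth_coupled"`, `"strong"`.
#' @export
classifyCoupling <- function(curve, tol = .TOL_ZERO) {
  k <- length(curve@biomassGrid)
  minAtZero <- curve@minProduction[1]
  minAtMax <- curve@minProduction[k]
  if (minAtZero > tol) "strong"
  else if (minAtMax > tol) "growth_coupled"
  else "none"
}

setMethod("show", "EnvelopeCurve", function(object) {
  cat("EnvelopeCurve:", length(object@biomassGrid), "points, growth in [0,",
      signif(max(object@biomassGrid), 6), "], class:", object@couplingClass, "\n")
})

#' Export an envelope as TSV
#'
#' Columns: `biomass`, `min_production`, `max_production`.
#' @param curve an [EnvelopeCurve-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEnvelopeTsv <- function(curve, path) {
  utils::write.table(
    data.frame(biomass = curve@biomassGrid,
               min_production = curve@minProduction,
               max_production = curve@maxProduction),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
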