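#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' MetabolicModel: a constraint-based metabolic network
#'
#' Container for a stoichiometric model: the sparse m x n stoichiometric
#' matrix `S`, per-reaction flux bounds (mmol/gDW/h), the linear objective
#' selecting the biomass reaction, and per-metabolite / per-reaction
#' annotation (chemical formulas, subsystems, gene-association rules).
#' Reversible reactions keep signed bounds (`lb < 0` allowed); no
#' irreversible splitting is performed anywhere in the package.
#'
#' A reaction is an exchange (boundary) reaction iff its column of `S` has
#' exactly one nonzero entry; see [exchangeReactions()].
#'
#' @slot metaboliteIds character, metabolite identifiers (rows of `S`).
#' @slot reactionIds character, reaction identifiers (columns of `S`).
#' @slot S sparse stoichiometric matrix (`dgCMatrix`).
#' @slot lb,ub numeric flux bounds, mmol/gDW/h.
#' @slot objective numeric objective weights; nonzero for the biomass reaction.
#' @slot biomassIndex integer position of the biomass reaction.
#' @slot formulas character chemical formula per metabolite (may be `""`).
#' @slot subsystems character pathway label per reaction (may be `""`).
#' @slot geneRules character boolean gene-association rule per reaction.
#'
#' @export
setClass("MetabolicModel",
  slots = c(
    metaboliteIds = "character",
    reactionIds   = "character",
    S             = "dgCMatrix",
    lb            = "numeric",
    ub            = "numeric",
    objective     = "numeric",
    biomassIndex  = "integer",
    formulas      = "character",
    subsystems    = "character",
    geneRules     = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  m <- length(object@metaboliteIds)
  n <- length(object@reactionIds)
  msgs <- character()
  if (nrow(object@S) != m) msgs <- c(msgs, "nrow(S) != number of metabolites")
  if (ncol(object@S) != n) msgs <- c(msgs, "ncol(S) != number of reactions")
  for (sl in c("lb", "ub", "objective", "subsystems", "geneRules"))
    if (length(slot(object, sl)) != n)
      msgs <- c(msgs, sprintf("length(%s) != number of reactions", sl))
  if (length(object@formulas) != m)
    msgs <- c(msgs, "length(formulas) != number of metabolites")
  bad <- which(object@lb > object@ub + 1e-12)
  if (length(bad))
    msgs <- c(msgs, sprintf("lb > ub for reaction(s): %s",
                            paste(object@reactionIds[bad], collapse = ", ")))
  if (anyDuplicated(object@reactionIds))
    msgs <- c(msgs, "duplicated reaction ids")
  if (anyDuplicated(object@metaboliteIds))
    msgs <- c(msgs, "duplicated metabolite ids")
  bi <- object@biomassIndex
  if (length(bi) != 1L || is.na(bi) || bi < 1L || bi > n)
    msgs <- c(msgs, "biomassIndex out of range")
  else if (object@objective[bi] == 0)
    msgs <- c(msgs, "biomass reaction has zero objective weight")
  if (length(msgs)) msgs else TRUE
})

#' DesignVector: a knockout design over a candidate set
#'
#' Binary vector `y` over the candidate reaction positions; `y[j] = 1`
#' means candidate `j` is knocked out.  At most `K` knockouts are allowed.
#'
#' @slot y integer 0/1 vector over candidates.
#' @slot candidates integer, distinct positions into the model's reactions.
#' @slot K integer, maximum allowable number of knockouts.
#' @export
setClass("DesignVector",
  slots = c(y = "integer", candidates = "integer", K = "integer")
)

setValidity("DesignVector", function(object) {
  msgs <- character()
  if (length(object@y) != length(object@candidates))
    msgs <- c(msgs, "length(y) != length(candidates)")
  if (!all(object@y %in% c(0L, 1L)))
    msgs <- c(msgs, "y must be binary")
  if (anyDuplicated(object@candidates))
    msgs <- c(msgs, "candidate indices must be distinct")
  if (sum(object@y) > object@K)
    msgs <- c(msgs, "sum(y) exceeds K")
  if (length(msgs)) msgs else TRUE
})

#' CandidateSet: knockout candidate reactions
#'
#' @slot indices integer positions into the model's reactions.
#' @slot nC numeric carbon cutoff used during selection (>= 100 disables).
#' @slot removalCounts named integer, reactions removed per exclusion rule.
#' @export
setClass("CandidateSet",
  slots = c(indices = "integer", nC = "numeric", removalCounts = "integer")
)

setValidity("CandidateSet", function(object) {
  if (anyDuplicated(object@indices)) "candidate indices must be distinct" else TRUE
})

#' FluxSolution: result of an LP flux computation
#'
#' @slot v numeric flux vector (mmol/gDW/h); empty when not optimal.
#' @slot objectiveValue numeric scalar.
#' @slot status `"optimal"`, `"infeasible"` or `"unbounded"`.
#' @slot duals numeric per-metabolite dual values (empty if unavailable).
#' @export
setClass("FluxSolution",
  slots = c(v = "numeric", objectiveValue = "numeric",
            status = "character", duals = "numeric")
)

#' EnvelopeCurve: a production envelope
#'
#' Minimum and maximum target flux while biomass is fixed (by equality) to
#' each value of an increasing grid spanning 0 to the design's maximum
#' growth.
#'
#' @slot biomassGrid numeric increasing growth values (1/h).
#' @slot minProduction,maxProduction numeric target fluxes per grid point.
#' @slot couplingClass `"none"`, `"growth_coupled"` or `"strong"`.
#' @export
setClass("EnvelopeCurve",
  slots = c(biomassGrid = "numeric", minProduction = "numeric",
            maxProduction = "numeric", couplingClass = "character")
)

setValidity("EnvelopeCurve", function(object) {
  msgs <- character()
  if (length(object@minProduction) != length(object@biomassGrid) ||
      length(object@maxProduction) != length(object@biomassGrid))
    msgs <- c(msgs, "grid and production vectors differ in length")
  if (is.unsorted(object@biomassGrid))
    msgs <- c(msgs, "biomassGrid must be increasing")
  if (any(object@minProduction > object@maxProduction + 1e-6))
    msgs <- c(msgs, "minProduction exceeds maxProduction")
  if (length(msgs)) msgs else TRUE
})

#' SingleLevelMILP: duality-reformulated interdiction MILP
#'
#' The max-min interdiction model with Lagrangian-penalised follower,
#' reformulated to a single-level MILP by LP duality: variables
#' `x = (v, u, lambda, alpha, beta, gamma, rho, sigma, delta)` and binary
#' `y` over candidates, constraints `Seq x = 0` and `A x + B y <= b`,
#' objective `cbar' x` (the target flux).
#'
#' @slot cbar numeric objective over `x`.
#' @slot Seq sparse equality block (steady-state rows).
#' @slot A,B sparse inequality blocks; `b` numeric offsets.
#' @slot lowerX,upperX numeric variable bounds on `x`.
#' @slot blocks named list of column/row index ranges for the blocks.
#' @slot candidates integer candidate reaction positions (columns of `B`).
#' @slot K integer knockout budget.
#' @slot penalties numeric Lagrange multipliers M over candidates.
#' @slot U numeric per-reaction flux magnitude caps max(|lb|,|ub|).
#' @slot targetIndex integer target reaction position.
#' @slot growthFloor numeric minimum biomass flux (1/h).
#' @export
setClass("SingleLevelMILP",
  slots = c(cbar = "numeric", Seq = "dgCMatrix",
            A = "dgCMatrix", B = "dgCMatrix", b = "numeric",
            lowerX = "numeric", upperX = "numeric",
            blocks = "list", candidates = "integer", K = "integer",
            penalties = "numeric", U = "numeric",
            targetIndex = "integer", growthFloor = "numeric")
)

#' BendersCut: affine constraint in (z, y) from a slave dual solution
#'
#' Optimality cuts read `z <= constant + coefficients' y`; feasibility cuts
#' read `constant + coefficients' y >= 0`.
#'
#' @slot kind `"optimality"` or `"feasibility"`.
#' @slot constant numeric `b' pi`.
#' @slot coefficients numeric `-(B' pi)` over candidates.
#' @slot pi numeric dual vector (extreme point or ray) over rows of `A`.
#' @slot value numeric slave value at the generating design (NA for
#'   feasibility cuts).
#' @slot yBar integer generating design.
#' @export
setClass("BendersCut",
  slots = c(kind = "character", constant = "numeric",
            coefficients = "numeric", pi = "numeric",
            value = "numeric", yBar = "integer")
)

#' SolutionRecord: an evaluated knockout design
#'
#' @slot design [DesignVector-class].
#' @slot knockoutIds character reaction ids knocked out.
#' @slot valueGuaranteed numeric guaranteed minimum production at the growth
#'   floor (the interdiction objective), mmol/gDW/h.
#' @slot growth numeric maximum growth of the mutant (1/h).
#' @slot minProduction,maxProduction numeric target flux range at the
#'   mutant's optimal growth (mmol/gDW/h).
#' @slot pctTmp numeric, 100 * minProduction / TMP.
#' @slot couplingClass `"none"`, `"growth_coupled"` or `"strong"`.
#' @slot envelope an [EnvelopeCurve-class] or `NULL`.
#' @export
setClass("SolutionRecord",
  slots = c(design = "DesignVector", knockoutIds = "character",
            valueGuaranteed = "numeric", growth = "numeric",
            minProduction = "numeric", maxProduction = "numeric",
            pctTmp = "numeric", couplingClass = "character",
            envelope = "ANY")
)
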