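#' @include AllGenerics.R
NULL

#' Construct a MetabolicModel
#'
#' @param metaboliteIds,reactionIds character identifiers.
#' @param S stoichiometric matrix (anything coercible to sparse).
#' @param lb,ub numeric flux bounds (mmol/gDW/h).
#' @param objective numeric objective weights (nonzero on biomass); if
#'   missing, `biomassIndex` must be given and gets weight 1.
#' @param biomassIndex biomass reaction position or id; defaults to the
#'   first reaction with a nonzero objective weight.
#' @param formulas,subsystems,geneRules optional annotation; default empty.
#' @return a validated [MetabolicModel-class]
#' @examples
#' toy <- makeToyNetwork("toy5")
#' nReactions(toy)
#' @export
MetabolicModel <- function(metaboliteIds, reactionIds, S, lb, ub,
                           objective = NULL, biomassIndex = NULL,
                           formulas = NULL, subsystems = NULL,
                           geneRules = NULL) {
  S <- as(as(as(Matrix::Matrix(S, sparse = TRUE), "dMatrix"), "generalMatrix"),
          "CsparseMatrix")
  n <- length(reactionIds)
  m <- length(metaboliteIds)
  if (is.character(biomassIndex))
    biomassIndex <- match(biomassIndex, reactionIds)
  if (is.null(objective)) {
    if (is.null(biomassIndex))
      stop("either objective weights or a biomass reaction must be given")
    objective <- numeric(n)
    objective[biomassIndex] <- 1
  }
  if (is.null(biomassIndex)) {
    nz <- which(objective != 0)
    if (!length(nz))
      stop("configuration error: model has no objective (biomass) reaction")
    biomassIndex <- nz[1L]
  }
  new("MetabolicModel",
      metaboliteIds = as.character(metaboliteIds),
      reactionIds = as.character(reactionIds),
      S = S, lb = as.numeric(lb), ub = as.numeric(ub),
      objective = as.numeric(objective),
      biomassIndex = as.integer(biomassIndex),
      formulas = if (is.null(formulas)) character(m) else as.character(formulas),
      subsystems = if (is.null(subsystems)) character(n) else as.character(subsystems),
      geneRules = if (is.null(geneRules)) character(n) else as.character(geneRules))
}

#' @rdname nReactions
#' @export
setMethod("nReactions", "MetabolicModel", function(object) length(object@reactionIds))

#' @rdname nReactions
#' @export
setMethod("nMetabolites", "MetabolicModel", function(object) length(object@metaboliteIds))

#' @rdname reactionIds
#' @export
setMethod("reactionIds", "MetabolicModel", function(object) object@reactionIds)

#' @rdname metaboliteIds
#' @export
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metaboliteIds)

#' @rdname stoichiometry
#' @export
setMethod("stoichiometry", "MetabolicModel", function(object) object@S)

#' @rdname fluxBounds
#' @export
setMethod("fluxBounds", "MetabolicModel", function(object) {
  cbind(lb = object@lb, ub = object@ub)
})

#' @rdname biomassReaction
#' @export
setMethod("biomassReaction", "MetabolicModel", function(object) object@biomassIndex)

#' @rdname exchangeReactions
#' @export
setMethod("exchangeReactions", "MetabolicModel", function(object) {
  Matrix::colSums(object@S != 0) == 1
})

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nMetabolites(object), "metabolites x",
      nReactions(object), "reactions\n")
  cat("  biomass:", object@reactionIds[object@biomassIndex], "\n")
  cat("  exchanges:", sum(exchangeReactions(object)),
      " reversible:", sum(object@lb < 0), "\n")
})

#' Resolve reaction ids/positions to integer positions
#' @noRd
.rxnIndex <- function(model, rxn) {
  if (is.character(rxn)) {
    idx <- match(rxn, model@reactionIds)
    if (anyNA(idx))
      stop("unknown reaction id(s): ", paste(rxn[is.na(idx)], collapse = ", "))
    return(as.integer(idx))
  }
  idx <- as.integer(rxn)
  if (any(idx < 1L | idx > nReactions(model)))
    stop("reaction index out of range")
  idx
}

#' Construct a DesignVector
#'
#' @param knockouts reaction positions or ids to knock out (subset of
#'   `candidates`).
#' @param candidates candidate reaction positions or ids.
#' @param K knockout budget; defaults to `length(knockouts)`.
#' @param model optional [MetabolicModel-class] used to resolve ids.
#' @return a [DesignVector-class]
#' @export
designVector <- function(knockouts = integer(), candidates = knockouts,
                         K = NULL, model = NULL) {
  if (!is.null(model)) {
    knockouts <- .rxnIndex(model, knockouts)
    candidates <- .rxnIndex(model, candidates)
  }
  candidates <- as.integer(candidates)
  knockouts <- as.integer(knockouts)
  if (!all(knockouts %in% candidates))
    stop("knockouts must lie inside the candidate list")
  if (is.null(K)) K <- length(knockouts)
  new("DesignVector", y = as.integer(candidates %in% knockouts),
      candidates = candidates, K = as.integer(K))
}

#' @rdname knockedReactions
#' @export
setMethod("knockedReactions", "DesignVector", function(object) {
  object@candidates[object@y == 1L]
})

#' @rdname knockedReactions
#' @export
setMethod("knockedReactions", "SolutionRecord", function(object) {
  knockedReactions(object@design)
})

setMethod("show", "DesignVector", function(object) {
  cat("DesignVector:", sum(object@y), "of up to", object@K,
      "knockouts over", length(object@candidates), "candidates\n")
})

#' @rdname applyKnockouts
#' @export
setMethod("applyKnockouts", signature("MetabolicModel", "DesignVector"),
  function(model, design) {
    ko <- knockedReactions(design)
    if (any(ko < 1L | ko > nReactions(model)))
      stop("design indices outside the model's reactions")
    model@lb[ko] <- 0
    model@ub[ko] <- 0
    model
  })

#' @rdname applyKnockouts
#' @export
setMethod("applyKnockouts", signature("MetabolicModel", "numeric"),
  function(model, design) {
    ko <- .rxnIndex(model, design)
    model@lb[ko] <- 0
    model@ub[ko] <- 0
    model
  })

#' @rdname applyKnockouts
#' @export
setMethod("applyKnockouts", signature("MetabolicModel", "character"),
  function(model, design) {
    applyKnockouts(model, .rxnIndex(model, design))
  })

#' Construct a CandidateSet
#' @param indices integer candidate reaction positions.
#' @param nC carbon cutoff recorded with the set.
#' @param removalCounts named integer of per-rule removals.
#' @export
candidateSet <- function(indices, nC = 100, removalCounts = integer()) {
  new("CandidateSet", indices = as.integer(indices), nC = as.numeric(nC),
      removalCounts = as.integer(removalCounts) |>
        stats::setNames(names(removalCounts)))
}

#' Size of a candidate set
#' @param x a [CandidateSet-class]
#' @export
setMethod("length", "CandidateSet", function(x) length(x@indices))

setMethod("show", "CandidateSet", function(object) {
  cat("CandidateSet: n_s =", length(object@indices),
      " (n_c =", object@nC, ")\n")
  if (length(object@removalCounts)) {
    cat("  removed per rule:\n")
    for (nm in names(object@removalCounts))
      cat("   ", nm, ":", object@removalCounts[[nm]], "\n")
  }
})

setMethod("show", "SolutionRecord", function(object) {
  cat(sprintf("SolutionRecord: {%s}  guaranteed min %.4f  growth %.4f  [%.4f, %.4f] at opt growth  %.1f%% TMP  %s\n",
              paste(object@knockoutIds, collapse = ", "),
              object@valueGuaranteed, object@growth,
              object@minProduction, object@maxProduction,
              object@pctTmp, object@couplingClass))
})
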