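#' @include fba.R
NULL

#' Carbon atoms in a chemical formula
#'
#' Parses an element-count formula in Hill notation (element symbol plus
#' optional integer count, e.g. `"C6H12O6"`) and returns the number of
#' carbon atoms.  An empty or missing formula counts as 0 carbons, with a
#' warning; malformed formulas raise a parse error.
#'
#' @param formula chemical formula string (vectorised).
#' @return integer carbon counts.
#' @examples
#' carbonCount("C6H12O6")   # 6
#' carbonCount("H2O")       # 0
#' @export
carbonCount <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) {
      warning("empty or unknown formula treated as 0 carbons")
      return(0L)
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f))
      stop("malformed chemical formula: ", f)
    cnt <- 0L
    for (t in toks) {
      el <- sub("^([A-Z][a-z]?).*$", "\\1", t)
      num <- sub("^[A-Z][a-z]?", "", t)
      if (el == "C") cnt <- cnt + if (nzchar(num)) as.integer(num) else 1L
    }
    cnt
  }, integer(1), USE.NAMES = FALSE)
}

# flux range of every reaction over {Sv = 0, lb <= v <= ub}
.fluxRanges <- function(model) {
  n <- nReactions(model)
  lo <- hi <- numeric(n)
  for (j in seq_len(n)) {
    lo[j] <- solveFBA(model, j, "min")@objectiveValue
    hi[j] <- solveFBA(model, j, "max")@objectiveValue
  }
  cbind(min = lo, max = hi)
}

#' Remove dead-end reactions
#'
#' Iteratively removes reactions whose feasible flux range is exactly
#' \{0\} (blocked reactions), together with metabolites left without any
#' reaction, until a fixed point is reached.  The biomass FBA optimum is
#' unchanged by construction.
#'
#' @param model a feasible [MetabolicModel-class].
#' @param tol zero-flux tolerance.
#' @return `list(model = reduced model, removed = character reaction ids)`
#' @export
removeDeadEnds <- function(model, tol = .TOL_ZERO) {
  removed <- character()
  repeat {
    rng <- .fluxRanges(model)
    blocked <- which(abs(rng[, "min"]) <= tol & abs(rng[, "max"]) <= tol)
    blocked <- setdiff(blocked, model@biomassIndex)
    if (!length(blocked)) break
    removed <- c(removed, model@reactionIds[blocked])
    model <- .dropReactions(model, blocked)
  }
  list(model = model, removed = removed)
}

.dropReactions <- function(model, idx) {
  keep <- setdiff(seq_len(nReactions(model)), idx)
  S <- model@S[, keep, drop = FALSE]
  keepMet <- which(Matrix::rowSums(S != 0) > 0)
  MetabolicModel(model@metaboliteIds[keepMet], model@reactionIds[keep],
                 S[keepMet, , drop = FALSE],
                 model@lb[keep], model@ub[keep],
                 objective = model@objective[keep],
                 formulas = model@formulas[keepMet],
                 subsystems = model@subsystems[keep],
                 geneRules = model@geneRules[keep])
}

#' Compress linear reaction chains
#'
#' Merges maximal chains in which an internal metabolite has exactly one
#' producing and one consuming reaction into single pseudo-reactions with
#' combined stoichiometry and intersected (flux-scaled) bounds.  Only
#' irreversible (`lb >= 0`) reaction pairs are merged, and protected
#' reactions — by default the biomass reaction and all exchange reactions,
#' so that sinks are never merged into the biomass or a target export —
#' are left untouched.  The merged-id mapping allows knockouts found on the
#' compressed model to be reported in original reaction ids.
#'
#' @param model a [MetabolicModel-class].
#' @param protect reaction ids/positions never to merge; defaults to the
#'   biomass reaction plus all exchange reactions.
#' @return `list(model = compressed model, mapping = named list
#'   merged-id -> character vector of original ids)`
#' @export
compressLinearChains <- function(model, protect = NULL) {
  protIdx <- if (is.null(protect)) {
    unique(c(model@biomassIndex, which(exchangeReactions(model))))
  } else .rxnIndex(model, protect)
  protIds <- model@reactionIds[protIdx]
  mapping <- stats::setNames(as.list(model@reactionIds), model@reactionIds)
  repeat {
    S <- model@S
    merged <- FALSE
    for (i in seq_len(nMetabolites(model))) {
      row <- S[i, ]
      nz <- which(row != 0)
      if (length(nz) != 2L) next
      signs <- sign(row[nz])
      if (sum(signs > 0) != 1L || sum(signs < 0) != 1L) next
      p <- nz[signs > 0]; cns <- nz[signs < 0]
      ids <- model@reactionIds[c(p, cns)]
      if (any(ids %in% protIds)) next
      if (model@lb[p] < 0 || model@lb[cns] < 0) next  # keep reversibles intact
      scale <- S[i, p] / (-S[i, cns])                  # v_cns = scale * v_p
      newCol <- S[, p] + scale * S[, cns]
      lbNew <- max(model@lb[p], model@lb[cns] / scale)
      ubNew <- min(model@ub[p], model@ub[cns] / scale)
      if (lbNew > ubNew) next
      newId <- paste(model@reactionIds[p], model@reactionIds[cns], sep = "__")
      S[, p] <- newCol
      model@S <- S
      model@reactionIds[p] <- newId
      model@lb[p] <- lbNew; model@ub[p] <- ubNew
      model@subsystems[p] <- model@subsystems[p]
      gr <- c(model@geneRules[p], model@geneRules[cns])
      gr <- gr[nzchar(gr)]
      model@geneRules[p] <- if (length(gr) > 1)
        paste0("(", gr[1], ") and (", gr[2], ")") else
        if (length(gr)) gr else ""
      mapping[[newId]] <- unique(c(mapping[[ids[1]]], mapping[[ids[2]]]))
      mapping[[ids[1]]] <- NULL
      if (ids[2] != ids[1]) mapping[[ids[2]]] <- NULL
      model <- .dropReactions(model, cns)
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  validObject(model)
  list(model = model, mapping = mapping)
}

#' Essential reactions at a growth floor
#'
#' Reactions whose single knockout drops the maximum growth strictly below
#' `growthFloor`.
#'
#' @param model a [MetabolicModel-class] with wild-type max growth `>=
#'   growthFloor`.
#' @param growthFloor minimum biomass flux (1/h).
#' @return character vector of reaction ids.
#' @export
essentialReactions <- function(model, growthFloor) {
  wt <- solveFBA(model)
  if (wt@status != "optimal")
    stop("wild-type model is ", wt@status)
  if (wt@objectiveValue < growthFloor)
    stop("wild-type growth below the requested floor")
  ess <- character()
  for (j in seq_len(nReactions(model))) {
    ko <- applyKnockouts(model, j)
    sol <- solveFBA(ko)
    if (sol@status != "optimal" || sol@objectiveValue < growthFloor - .TOL_ZERO)
      ess <- c(ess, model@reactionIds[j])
  }
  ess
}

#' Select candidate knockout reactions
#'
#' Starts from all reactions and excludes, in order: the biomass reaction;
#' the target reaction; all exchange reactions (the substrate uptake among
#' them), except the oxygen exchange when `keepOxygen` is set; reactions
#' without a gene-association rule (when `requireGeneRule`); reactions
#' essential at `growthFloor`; user-specified exclusions; and any reaction
#' with a participating metabolite (substrate or product) of more than
#' `nC` carbon atoms.  `nC >= 100` disables the carbon filter.  Per-rule
#' removal counts are recorded on the returned set and logged as messages.
#'
#' @param model a [MetabolicModel-class].
#' @param target target reaction position or id.
#' @param nC carbon cutoff (default 100 = filter off).
#' @param growthFloor minimum growth for the essentiality screen (1/h).
#' @param keepOxygen keep the oxygen exchange as a candidate (default TRUE;
#'   anaerobic-switch designs knock it out).
#' @param requireGeneRule exclude reactions without gene rules (default
#'   TRUE; spontaneous/boundary pseudo-reactions cannot be knocked out).
#' @param userExcludes reaction ids to exclude; unknown ids are warned
#'   about and ignored.
#' @return a [CandidateSet-class]
#' @export
selectCandidates <- function(model, target, nC = 100, growthFloor = 0,
                             keepOxygen = TRUE, requireGeneRule = TRUE,
                             userExcludes = character()) {
  tIdx <- .rxnIndex(model, target)
  n <- nReactions(model)
  keep <- rep(TRUE, n)
  counts <- integer()
  note <- function(rule, removedNow) {
    counts[[rule]] <<- as.integer(removedNow)
    message(sprintf("candidate selection: %-14s removed %d", rule, removedNow))
  }
  drop1 <- function(sel, rule) {
    sel <- sel & keep
    note(rule, sum(sel))
    keep[sel] <<- FALSE
  }
  drop1(seq_len(n) == model@biomassIndex, "biomass")
  drop1(seq_len(n) == tIdx, "target")
  ex <- exchangeReactions(model)
  if (keepOxygen) {
    o2 <- ex & vapply(seq_len(n), function(j) {
      met <- which(model@S[, j] != 0)
      length(met) == 1 && identical(model@formulas[met], "O2")
    }, logical(1))
    ex <- ex & !o2
  }
  drop1(ex, "exchange")
  if (requireGeneRule) drop1(!nzchar(model@geneRules), "no_gene_rule")
  essIds <- essentialReactions(model, growthFloor)
  drop1(model@reactionIds %in% essIds, "essential")
  if (length(userExcludes)) {
    unknown <- setdiff(userExcludes, model@reactionIds)
    if (length(unknown))
      warning("user exclusions not in model: ", paste(unknown, collapse = ", "))
    drop1(model@reactionIds %in% userExcludes, "user")
  }
  if (nC < 100) {
    metC <- carbonCount(ifelse(nzchar(model@formulas), model@formulas, "H"))
    highC <- vapply(seq_len(n), function(j) {
      any(metC[which(model@S[, j] != 0)] > nC)
    }, logical(1))
    drop1(highC, "carbon")
  }
  idx <- which(keep)
  if (!length(idx))
    stop("empty candidate set; consider a larger carbon cutoff n_c")
  candidateSet(idx, nC = nC, removalCounts = counts)
}
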