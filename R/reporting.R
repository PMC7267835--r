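#' @include hba.R
NULL

#' Evaluate a knockout design into a solution record
#'
#' Computes the knocked-out model's maximal growth, the minimum and
#' maximum target flux at that growth (biomass fixed by equality), the
#' percent of theoretical maximum production (`100 * minProduction /
#' TMP`), and the growth-coupling class (from the envelope endpoints at
#' zero and maximal growth).
#'
#' @param model a [MetabolicModel-class] (wild type; the design is applied
#'   internally).
#' @param design a [DesignVector-class].
#' @param target target reaction position or id.
#' @param tmp the theoretical maximum production; computed when `NULL`.
#' @param growthFloor when given, the guaranteed minimum production at
#'   this floor ([followerMinProduction()]) is stored in
#'   `valueGuaranteed`; otherwise it is `NA`.
#' @param envelope attach the full [productionEnvelope()] (`nPoints`
#'   points) to the record.
#' @param nPoints grid size for the attached envelope.
#' @return a [SolutionRecord-class]
#' @export
evaluateRecord <- function(model, design, target, tmp = NULL,
                           growthFloor = NULL, envelope = FALSE,
                           nPoints = 20) {
  tIdx <- .rxnIndex(model, target)
  if (is.null(tmp)) tmp <- theoreticalMaxProduction(model, tIdx)
  ko <- applyKnockouts(model, design)
  gsol <- solveFBA(ko)
  if (gsol@status != "optimal")
    stop("design is infeasible; cannot evaluate")
  gmax <- gsol@objectiveValue
  bio <- ko@reactionIds[ko@biomassIndex]
  atB <- function(b, sense) {
    fix <- list(c(b, b)); names(fix) <- bio
    solveFBA(ko, tIdx, sense, extraBounds = fix)@objectiveValue
  }
  minAtOpt <- atB(gmax, "min"); maxAtOpt <- atB(gmax, "max")
  minAtZero <- atB(0, "min"); maxAtZero <- atB(0, "max")
  curve <- new("EnvelopeCurve", biomassGrid = c(0, gmax),
               minProduction = c(minAtZero, minAtOpt),
               maxProduction = c(maxAtZero, maxAtOpt),
               couplingClass = "none")
  cls <- classifyCoupling(curve)
  env <- if (envelope) productionEnvelope(model, tIdx, design, nPoints)
         else NULL
  guaranteed <- if (is.null(growthFloor)) NA_real_ else {
    sol <- followerMinProduction(model, tIdx, design, growthFloor)
    if (sol@status == "optimal") sol@objectiveValue else NA_real_
  }
  new("SolutionRecord", design = design,
      knockoutIds = model@reactionIds[knockedReactions(design)],
      valueGuaranteed = guaranteed, growth = gmax,
      minProduction = minAtOpt, maxProduction = maxAtOpt,
      pctTmp = if (tmp > 0) 100 * minAtOpt / tmp else 0,
      couplingClass = cls, envelope = env)
}

#' Filter, deduplicate and order a solution pool
#'
#' Keeps records whose minimum production at optimal growth reaches
#' `thresholdFraction` of the theoretical maximum (i.e. `pctTmp >= 100 *
#' thresholdFraction`), collapses duplicate designs, and orders by
#' minimum production descending, ties broken lexicographically on the
#' knocked-out reaction ids.  Idempotent.
#'
#' @param pool list of [SolutionRecord-class].
#' @param thresholdFraction in `[0, 1]`.
#' @return the filtered list.
#' @export
filterPool <- function(pool, thresholdFraction = 0) {
  stopifnot(thresholdFraction >= 0, thresholdFraction <= 1)
  if (!length(pool)) return(pool)
  keep <- vapply(pool, function(r) r@pctTmp >= 100 * thresholdFraction - 1e-9,
                 logical(1))
  pool <- pool[keep]
  if (!length(pool)) return(pool)
  keys <- vapply(pool, function(r) paste(sort(knockedReactions(r)),
                                         collapse = "+"), "")
  pool <- pool[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  vals <- vapply(pool, function(r) r@minProduction, numeric(1))
  pool[order(-vals, keys)]
}

#' Knockout and subsystem frequencies over a solution pool
#'
#' Per reaction: the fraction of designs that knock it out.  Per
#' subsystem: the fraction of designs with at least one knockout in that
#' subsystem.
#'
#' @param pool nonempty list of [SolutionRecord-class].
#' @param model the [MetabolicModel-class] the designs refer to.
#' @return `list(perReaction, perSubsystem)`, two data frames with
#'   columns (`reaction`|`subsystem`, `fraction`), ordered by decreasing
#'   fraction.
#' @export
knockoutFrequency <- function(pool, model) {
  if (!length(pool)) stop("empty solution pool")
  nsol <- length(pool)
  rxnCount <- integer(nReactions(model))
  subHit <- stats::setNames(integer(length(unique(model@subsystems))),
                            unique(model@subsystems))
  for (rec in pool) {
    ko <- knockedReactions(rec)
    rxnCount[ko] <- rxnCount[ko] + 1L
    for (s in unique(model@subsystems[ko]))
      subHit[[s]] <- subHit[[s]] + 1L
  }
  pr <- data.frame(reaction = model@reactionIds,
                   fraction = rxnCount / nsol)
  pr <- pr[order(-pr$fraction, pr$reaction), ]
  rownames(pr) <- NULL
  ps <- data.frame(subsystem = names(subHit),
                   fraction = as.numeric(subHit) / nsol)
  ps <- ps[order(-ps$fraction, ps$subsystem), ]
  rownames(ps) <- NULL
  list(perReaction = pr, perSubsystem = ps)
}

#' Export a solution pool as TSV
#'
#' Columns: knocked-out reaction ids (`+`-separated), guaranteed minimum
#' production at the growth floor, growth at solution, min/max production
#' at optimal growth, percent TMP, coupling class.
#'
#' @param pool list of [SolutionRecord-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSolutionsTsv <- function(pool, path) {
  df <- do.call(rbind, lapply(pool, function(r) {
    data.frame(knockouts = paste(r@knockoutIds, collapse = "+"),
               guaranteed_min_production = r@valueGuaranteed,
               growth = r@growth,
               min_production = r@minProduction,
               max_production = r@maxProduction,
               pct_tmp = r@pctTmp,
               coupling = r@couplingClass)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export knockout/subsystem frequency tables as TSV
#' @param freq result of [knockoutFrequency()].
#' @param pathReaction,pathSubsystem output files.
#' @return invisibly, the two paths.
#' @export
writeFrequencyTsv <- function(freq, pathReaction, pathSubsystem) {
  utils::write.table(freq$perReaction, pathReaction, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(freq$perSubsystem, pathSubsystem, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(pathReaction, pathSubsystem))
}
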