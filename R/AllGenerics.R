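#' @include AllClasses.R
NULL

#' Number of reactions / metabolites
#' @param object a [MetabolicModel-class]
#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))

#' @rdname nReactions
#' @export
setGeneric("nMetabolites", function(object) standardGeneric("nMetabolites"))

#' Reaction identifiers
#' @param object a [MetabolicModel-class]
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' Metabolite identifiers
#' @param object a [MetabolicModel-class]
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' Stoichiometric matrix
#' @param object a [MetabolicModel-class]
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' Flux bounds
#'
#' Two-column matrix of lower and upper flux bounds (mmol/gDW/h), one row
#' per reaction.
#' @param object a [MetabolicModel-class]
#' @export
setGeneric("fluxBounds", function(object) standardGeneric("fluxBounds"))

#' Biomass reaction position
#' @param object a [MetabolicModel-class]
#' @export
setGeneric("biomassReaction", function(object) standardGeneric("biomassReaction"))

#' Exchange (boundary) reaction flags
#'
#' `TRUE` for every reaction whose stoichiometric column has exactly one
#' nonzero entry, i.e. single-metabolite boundary reactions.
#' @param object a [MetabolicModel-class]
#' @export
setGeneric("exchangeReactions", function(object) standardGeneric("exchangeReactions"))

#' Knocked-out reaction positions of a design
#' @param object a [DesignVector-class] or [SolutionRecord-class]
#' @export
setGeneric("knockedReactions", function(object) standardGeneric("knockedReactions"))

#' Apply a knockout design to a model
#'
#' Returns a copy of the model in which every knocked-out reaction has both
#' flux bounds set to zero; the input model is unmodified.
#'
#' @param model a [MetabolicModel-class]
#' @param design a [DesignVector-class], or an integer/character vector of
#'   reaction positions/ids to knock out
#' @return a [MetabolicModel-class]
#' @export
setGeneric("applyKnockouts", function(model, design) standardGeneric("applyKnockouts"))
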