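#' @include MetabolicModel-methods.R
NULL

# SBML SIds must start with a letter/underscore; the community convention is
# to prefix metabolites with "M_" and reactions with "R_".  Ids are prefixed
# on write and stripped on read.
.sbmlId <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", id))
.stripSbmlId <- function(prefix, id) sub(paste0("^", prefix), "", id)

#' Load a metabolic model from file
#'
#' Reads a genome-scale model from SBML Level-3 with the FBC package, or
#' from COBRA-style JSON (`metabolites`/`reactions` arrays with
#' `lower_bound`, `upper_bound`, `objective_coefficient`).  Reversible
#' reactions keep signed bounds.  Unknown JSON fields are ignored with a
#' warning.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"sbml-fbc"` or `"cobra-json"`.
#' @return a [MetabolicModel-class]
#' @seealso [writeModel()]
#' @export
loadModel <- function(path, dialect = c("auto", "sbml-fbc", "cobra-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "cobra-json" else "sbml-fbc"
  }
  model <- switch(dialect,
                  "cobra-json" = .readCobraJson(path),
                  "sbml-fbc" = .readSbmlFbc(path))
  validObject(model)
  model
}

#' Write a metabolic model to file
#'
#' @param model a [MetabolicModel-class].
#' @param path output file path.
#' @param dialect `"auto"` (by extension), `"sbml-fbc"` or `"cobra-json"`.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path, dialect = c("auto", "sbml-fbc", "cobra-json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "cobra-json" else "sbml-fbc"
  }
  switch(dialect,
         "cobra-json" = .writeCobraJson(model, path),
         "sbml-fbc" = .writeSbmlFbc(model, path))
  invisible(path)
}

.readCobraJson <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  known <- c("metabolites", "reactions", "genes", "id", "name",
             "compartments", "version", "annotation", "notes")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    warning("ignoring unknown COBRA-JSON fields: ", paste(extra, collapse = ", "))
  mets <- doc$metabolites
  rxns <- doc$reactions
  if (is.null(mets) || is.null(rxns))
    stop("format error: COBRA-JSON must contain 'metabolites' and 'reactions' arrays")
  metIds <- vapply(mets, function(m) as.character(m$id), character(1))
  formulas <- vapply(mets, function(m)
    if (is.null(m$formula)) "" else as.character(m$formula), character(1))
  n <- length(rxns)
  rxnIds <- character(n); lb <- ub <- obj <- numeric(n)
  subsystems <- geneRules <- character(n)
  trip <- list()
  for (j in seq_len(n)) {
    r <- rxns[[j]]
    if (is.null(r$id)) stop("format error: reaction ", j, " has no id")
    rxnIds[j] <- as.character(r$id)
    lb[j] <- if (is.null(r$lower_bound)) -1000 else as.numeric(r$lower_bound)
    ub[j] <- if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound)
    if (lb[j] > ub[j])
      stop("format error: reaction ", rxnIds[j], " has lower_bound > upper_bound")
    obj[j] <- if (is.null(r$objective_coefficient)) 0 else
      as.numeric(r$objective_coefficient)
    subsystems[j] <- if (is.null(r$subsystem)) "" else as.character(r$subsystem)
    geneRules[j] <- if (is.null(r$gene_reaction_rule)) "" else
      as.character(r$gene_reaction_rule)
    for (met in names(r$metabolites)) {
      i <- match(met, metIds)
      if (is.na(i))
        stop("format error: reaction ", rxnIds[j], " references unknown metabolite ", met)
      trip[[length(trip) + 1L]] <- c(i, j, as.numeric(r$metabolites[[met]]))
    }
  }
  tm <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = tm[, 1], j = tm[, 2], x = tm[, 3],
                            dims = c(length(metIds), n))
  if (all(obj == 0))
    stop("configuration error: no objective reaction in model")
  MetabolicModel(metIds, rxnIds, S, lb, ub, objective = obj,
                 formulas = formulas, subsystems = subsystems,
                 geneRules = geneRules)
}

.writeCobraJson <- function(model, path) {
  S <- model@S
  mets <- lapply(seq_along(model@metaboliteIds), function(i) {
    list(id = model@metaboliteIds[i], formula = model@formulas[i],
         compartment = "c")
  })
  rxns <- lapply(seq_len(nReactions(model)), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    r <- list(id = model@reactionIds[j],
              metabolites = as.list(stats::setNames(col[nz], model@metaboliteIds[nz])),
              lower_bound = model@lb[j], upper_bound = model@ub[j],
              subsystem = model@subsystems[j],
              gene_reaction_rule = model@geneRules[j])
    if (model@objective[j] != 0) r$objective_coefficient <- model@objective[j]
    r
  })
  doc <- list(id = "model", metabolites = mets, reactions = rxns, genes = list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.writeSbmlFbc <- function(model, path) {
  fbcNs <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbcNs, level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model", "fbc:strict" = "true")
  cl <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(cl, "compartment", id = "c", constant = "true")
  sl <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_along(model@metaboliteIds)) {
    sp <- xml2::xml_add_child(sl, "species",
      id = .sbmlId("M_", model@metaboliteIds[i]),
      name = model@metaboliteIds[i], compartment = "c",
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (nzchar(model@formulas[i]))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", model@formulas[i])
  }
  pl <- xml2::xml_add_child(mdl, "listOfParameters")
  n <- nReactions(model)
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  for (j in seq_len(n)) {
    xml2::xml_add_child(pl, "parameter", id = paste0("lb_", j),
                        value = fmt(model@lb[j]), constant = "true")
    xml2::xml_add_child(pl, "parameter", id = paste0("ub_", j),
                        value = fmt(model@ub[j]), constant = "true")
  }
  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  S <- model@S
  for (j in seq_len(n)) {
    rx <- xml2::xml_add_child(rl, "reaction",
      id = .sbmlId("R_", model@reactionIds[j]),
      name = model@reactionIds[j],
      reversible = tolower(model@lb[j] < 0), fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", j),
      "fbc:upperFluxBound" = paste0("ub_", j))
    if (nzchar(model@subsystems[j]) || nzchar(model@geneRules[j])) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      if (nzchar(model@subsystems[j]))
        xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", model@subsystems[j]))
      if (nzchar(model@geneRules[j]))
        xml2::xml_add_child(body, "p", paste0("GENE_ASSOCIATION: ", model@geneRules[j]))
    }
    col <- S[, j]
    reac <- which(col < 0); prod <- which(col > 0)
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in reac)
        xml2::xml_add_child(lr, "speciesReference",
          species = .sbmlId("M_", model@metaboliteIds[i]),
          stoichiometry = fmt(-col[i]), constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in prod)
        xml2::xml_add_child(lp, "speciesReference",
          species = .sbmlId("M_", model@metaboliteIds[i]),
          stoichiometry = fmt(col[i]), constant = "true")
    }
  }
  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  for (j in which(model@objective != 0))
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = .sbmlId("R_", model@reactionIds[j]),
                        "fbc:coefficient" = fmt(model@objective[j]))
  xml2::write_xml(doc, path)
}

.readSbmlFbc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: not parseable XML: ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(species)) stop("format error: no species in SBML file")
  metIds <- .stripSbmlId("M_", xml2::xml_attr(species, "id"))
  formulas <- xml2::xml_attr(species, "chemicalFormula")
  formulas[is.na(formulas)] <- ""
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pv <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                        xml2::xml_attr(params, "id"))
  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rxns)) stop("format error: no reactions in SBML file")
  n <- length(rxns)
  rxnIds <- .stripSbmlId("R_", xml2::xml_attr(rxns, "id"))
  lb <- ub <- numeric(n)
  subsystems <- geneRules <- character(n)
  trip <- list()
  for (j in seq_len(n)) {
    rx <- rxns[[j]]
    lbRef <- xml2::xml_attr(rx, "lowerFluxBound")
    ubRef <- xml2::xml_attr(rx, "upperFluxBound")
    if (is.na(lbRef) || is.na(ubRef) || !(lbRef %in% names(pv)) ||
        !(ubRef %in% names(pv)))
      stop("format error: reaction ", rxnIds[j], " has unresolvable flux bounds")
    lb[j] <- pv[[lbRef]]; ub[j] <- pv[[ubRef]]
    if (lb[j] > ub[j])
      stop("format error: reaction ", rxnIds[j], " has lb > ub")
    ps <- xml2::xml_text(xml2::xml_find_all(rx, ".//s:notes//*[not(*)]", ns))
    sub <- grep("^SUBSYSTEM: ", ps, value = TRUE)
    if (length(sub)) subsystems[j] <- sub("^SUBSYSTEM: ", "", sub[1])
    ga <- grep("^GENE_ASSOCIATION: ", ps, value = TRUE)
    if (length(ga)) geneRules[j] <- sub("^GENE_ASSOCIATION: ", "", ga[1])
    for (sr in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns)) {
      i <- match(.stripSbmlId("M_", xml2::xml_attr(sr, "species")), metIds)
      trip[[length(trip) + 1L]] <-
        c(i, j, -as.numeric(xml2::xml_attr(sr, "stoichiometry")))
    }
    for (sr in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns)) {
      i <- match(.stripSbmlId("M_", xml2::xml_attr(sr, "species")), metIds)
      trip[[length(trip) + 1L]] <-
        c(i, j, as.numeric(xml2::xml_attr(sr, "stoichiometry")))
    }
  }
  tm <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = tm[, 1], j = tm[, 2], x = tm[, 3],
                            dims = c(length(metIds), n))
  fo <- xml2::xml_find_all(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (!length(fo))
    stop("configuration error: no objective reaction in SBML file")
  obj <- numeric(n)
  foRxn <- .stripSbmlId("R_", xml2::xml_attr(fo, "reaction"))
  obj[match(foRxn, rxnIds)] <- as.numeric(xml2::xml_attr(fo, "coefficient"))
  MetabolicModel(metIds, rxnIds, S, lb, ub, objective = obj,
                 formulas = formulas, subsystems = subsystems,
                 geneRules = geneRules)
}
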