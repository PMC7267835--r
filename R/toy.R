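#' @include MetabolicModel-methods.R
NULL

#' Synthetic toy metabolic networks
#'
#' Small mass-balanced fixture networks with a substrate uptake, a biomass
#' sink, a product export and both growth-coupled and uncoupled routes to
#' the product.  Two kinds are available:
#'
#' * `"toy5"` — the canonical five-reaction fixture: metabolites `A`, `B`,
#'   `C`; irreversible reactions `UP: -> A` (ub 10), `R1: A -> B`,
#'   `R3: A -> B + C`, `BIO: B ->` (biomass, objective) and `PRD: C ->`
#'   (target product export).  Knocking out `R1` forces all flux through
#'   `R3`, coupling product export to growth.
#' * `"random_branched"` — `nBranches` parallel two-step routes from the
#'   substrate to the biomass metabolite, of which a `coupledFraction`
#'   co-produce the product metabolite.  Stoichiometric coefficients are
#'   drawn from \{1, 2\} so small LP optima stay hand-checkable.  The same
#'   seed always yields the identical model.
#'
#' Every generated network has a feasible, strictly positive maximum
#' biomass flux, and every internal metabolite has at least one producer
#' and one consumer.
#'
#' @param kind `"toy5"` or `"random_branched"`.
#' @param nBranches number of parallel substrate-to-biomass routes (>= 1).
#' @param coupledFraction proportion of branches co-producing the product
#'   (in `[0, 1]`; at least one branch is always coupled so the product is
#'   reachable).
#' @param seed integer RNG seed for `"random_branched"`.
#' @param uptake substrate uptake cap, mmol/gDW/h.
#' @return a [MetabolicModel-class]
#' @examples
#' toy <- makeToyNetwork("toy5")
#' solveFBA(toy)@objectiveValue     # 10: uptake cap propagates to biomass
#' @export
makeToyNetwork <- function(kind = c("toy5", "random_branched"),
                           nBranches = 4, coupledFraction = 0.5,
                           seed = 1, uptake = 10) {
  kind <- match.arg(kind)
  if (kind == "toy5") return(.toy5(uptake))
  stopifnot(nBranches >= 1, coupledFraction >= 0, coupledFraction <= 1)
  .randomBranched(nBranches, coupledFraction, seed, uptake)
}

.toy5 <- function(uptake = 10) {
  mets <- c("A", "B", "C")
  rxns <- c("UP", "R1", "R3", "BIO", "PRD")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A", "UP"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["A", "R3"] <- -1; S["B", "R3"] <- 1; S["C", "R3"] <- 1
  S["B", "BIO"] <- -1
  S["C", "PRD"] <- -1
  MetabolicModel(mets, rxns, S,
                 lb = c(0, 0, 0, 0, 0),
                 ub = c(uptake, 1000, 1000, 1000, 1000),
                 biomassIndex = "BIO",
                 formulas = c("C3H4O3", "C3H7NO2", "C40H56"),
                 subsystems = c("Exchange", "Central", "Central",
                                "Biomass", "Exchange"),
                 geneRules = c("", "g1", "g3", "", ""))
}

.randomBranched <- function(nBranches, coupledFraction, seed, uptake) {
  withSeed(seed, {
    nCoupled <- max(1L, round(coupledFraction * nBranches))
    coupled <- sort(sample.int(nBranches, nCoupled))
    mets <- c("Sub", paste0("X", seq_len(nBranches)), "BM", "P")
    m <- length(mets)
    rxnIds <- c("UP")
    cols <- list(stats::setNames(c(1), "Sub"))
    lb <- c(0); ub <- c(uptake)
    sub <- c("Exchange")
    for (i in seq_len(nBranches)) {
      # step 1: Sub -> a X_i, coefficient a drawn from {1, 2}
      a <- sample(c(1, 2), 1)
      rxnIds <- c(rxnIds, sprintf("B%dA", i))
      cols <- c(cols, list(stats::setNames(c(-1, a), c("Sub", paste0("X", i)))))
      lb <- c(lb, 0); ub <- c(ub, 1000)
      sub <- c(sub, sprintf("Branch%d", i))
      # step 2: X_i -> BM (+ P when the branch is coupled)
      rxnIds <- c(rxnIds, sprintf("B%dB", i))
      cc <- c(-1, 1)
      nm <- c(paste0("X", i), "BM")
      if (i %in% coupled) { cc <- c(cc, 1); nm <- c(nm, "P") }
      cols <- c(cols, list(stats::setNames(cc, nm)))
      lb <- c(lb, 0); ub <- c(ub, 1000)
      sub <- c(sub, sprintf("Branch%d", i))
    }
    rxnIds <- c(rxnIds, "BIO", "PRD")
    cols <- c(cols, list(stats::setNames(c(-1), "BM")),
              list(stats::setNames(c(-1), "P")))
    lb <- c(lb, 0, 0); ub <- c(ub, 1000, 1000)
    sub <- c(sub, "Biomass", "Exchange")
    n <- length(rxnIds)
    S <- matrix(0, m, n, dimnames = list(mets, rxnIds))
    for (j in seq_len(n)) S[names(cols[[j]]), j] <- cols[[j]]
    formulas <- c("C6H12O6", rep("C3H4O3", nBranches), "", "C4H6O4")
    MetabolicModel(mets, rxnIds, S, lb, ub, biomassIndex = "BIO",
                   formulas = formulas, subsystems = sub,
                   geneRules = c("", paste0("g", seq_len(2 * nBranches)), "", ""))
  })
}
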