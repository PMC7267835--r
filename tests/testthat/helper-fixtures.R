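# fixtures shared across test files; everything is generated in code

toy5 <- makeToyNetwork("toy5")

# a small battery of branched fixtures with varying size and budget
fixtureGrid <- function(seeds) {
  lapply(seeds, function(s) {
    nb <- 2 + s %% 3                     # 2..4 branches -> 4..8 candidates
    model <- makeToyNetwork("random_branched", nBranches = nb,
                            coupledFraction = 0.5, seed = s)
    wt <- solveFBA(model)@objectiveValue
    floor <- 0.1 * wt
    cand <- suppressMessages(
      selectCandidates(model, "PRD", growthFloor = floor))
    list(model = model, cand = cand, K = 1 + s %% 3, floor = floor,
         seed = s)
  })
}

toy5Candidates <- function(floor = 1) {
  suppressMessages(selectCandidates(toy5, "PRD", growthFloor = floor,
                                    requireGeneRule = FALSE))
}

# random designs over a candidate set (allows the empty design)
randomDesigns <- function(cand, K, nDesigns, seed) {
  set.seed(seed)
  lapply(seq_len(nDesigns), function(i) {
    k <- sample(0:K, 1)
    ko <- if (k == 0) integer() else sample(cand@indices, k)
    designVector(as.integer(ko), cand@indices, K = K)
  })
}

# all binary vectors over nc candidates with at most K ones
enumerateDesigns <- function(nc, K) {
  out <- list()
  for (k in 0:min(K, nc)) {
    sets <- if (k == 0) list(integer()) else
      asplit(utils::combn(nc, k), 2)
    for (s in sets) {
      y <- integer(nc); y[s] <- 1L
      out[[length(out) + 1L]] <- y
    }
  }
  out
}
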