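# nihba — growth-coupled strain design by network interdiction

`nihba` finds reaction-knockout strategies that *force* a production
micro-organism to excrete a target chemical. It is aimed at metabolic
engineers working with genome-scale constraint-based models (SBML-FBC or
COBRA-JSON) who want many alternative growth-coupled designs from a single
run, without assuming that the mutant grows optimally.

## The model

Classical bilevel strain design (OptKnock and descendants) maximises
production *assuming* the mutant maximises growth. `nihba` instead treats
design as a **network interdiction game**: the host cell tries to keep the
target flux low (homoeostasis), the engineer removes up to `K` reactions to
push the *guaranteed minimum* production up,

```
max_{y ∈ Y}  min_v  c_P' v
s.t.  S v = 0,
      lb_j (1 - y_j) ≤ v_j ≤ ub_j (1 - y_j)   (j ∈ J̄, candidates)
      lb_j ≤ v_j ≤ ub_j                        (other reactions)
      v_biomass ≥ g_min,
      |{j : y_j = 1}| ≤ K,
```

where `S` is the stoichiometric matrix, `v` the flux vector (mmol/gDW/h),
`c_P` the indicator of the target exchange reaction and `g_min` a minimal
growth requirement (default 10% of wild type). The only objective is the
target flux itself — no growth-optimality bias.

The knockout constraints are folded into the inner objective as Lagrangian
penalties `Σ_j M_j |v_j| y_j` with `M_j ~ U[90, 110]`, linearised via
magnitude variables `u_j = max(v_j, −v_j)` and turned into a single-level
MILP by LP duality plus a strong-duality equality. The MILP is solved
either directly (`solveDirect()`, the baseline) or by a **hybrid Benders
algorithm** (`runHBA()`):

* a binary **master** over `(y, z)` accumulates optimality cuts
  `z ≤ (b − By)'π°` and feasibility cuts `(b − By)'π^f ≥ 0`;
* the **slave** LP at fixed `y` is solved with a core-point-perturbed
  right-hand side (`μ = 1e-8`) so every cut is Pareto-optimal;
* **local branching** restricts the master to Hamming balls
  `Δ_H(y, y′) ≤ r − 1` around the incumbent, reversing the ball when its
  bound is exhausted;
* the master stops early at the absolute gap `1 + 300/(√iter + 1)`;
* every feasible design met on the way is stored in a **solution pool**
  with its guaranteed minimum production, so one run yields many designs.

An exhaustive oracle (`bruteForceInterdiction()`) and the direct MILP
validate the Benders machinery on every desk-scale network.

## Worked example

The five-reaction demonstration network has metabolites `A, B, C` and
reactions `UP: → A` (uptake, cap 10), `R1: A → B`, `R3: A → B + C`,
`BIO: B →` (biomass) and `PRD: C →` (target). The wild type routes
everything through `R1` and produces nothing.

```r
library(nihba)
toy  <- makeToyNetwork("toy5")
cand <- selectCandidates(toy, "PRD", growthFloor = 1, requireGeneRule = FALSE)
res  <- runHBA(toy, cand, "PRD", hbaConfig(K = 1, growthFloor = 1))
res$best
#> SolutionRecord: {R1}  guaranteed min 1.0000  growth 10.0000  [10.0000, 10.0000] at opt growth  100.0% TMP  growth_coupled
```

Knocking out `R1` forces all uptake through `R3`, which co-produces `C`:
the guaranteed minimum production at the growth floor (1/h) is 1.0
mmol/gDW/h, and at the mutant's optimal growth (10/h) production is pinned
to 10 — 100% of the theoretical maximum (TMP, the FBA optimum with the
target as objective). The envelope confirms a growth-coupled design:

```r
productionEnvelope(toy, "PRD", res$best@design, nPoints = 3)
#> EnvelopeCurve: 3 points, growth in [0, 10 ], class: growth_coupled
```

A command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/nihba.R", package="nihba"))') \
    run --model model.json --target EX_succ_e --max-ko 5 --out out/
```

writing `solutions.tsv`, envelope and knockout-frequency tables and a
run-metadata JSON.

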