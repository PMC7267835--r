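---
title: "Strain design as network interdiction: model, algorithm and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain design as network interdiction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design problem

Constraint-based metabolic models describe a cell as a stoichiometric
matrix $S \in \mathbb{R}^{m \times n}$ over $m$ metabolites and $n$
reactions, with fluxes $v$ (mmol/gDW/h) constrained by steady state
($Sv = 0$) and bounds $lb \le v \le ub$. Flux balance analysis (FBA)
optimises a linear objective — usually biomass — over this polytope.

Knockout design is usually posed as a bilevel program in which the outer
level picks knockouts and the inner level *maximises growth*. That inner
assumption is biologically contentious for mutants. `nihba` drops it:
design is a max–min **interdiction game** in which the inner player
*minimises the target flux* subject only to a minimal growth requirement,
and the outer player chooses at most $K$ knockouts to raise that guaranteed
minimum. The optimum is the production level the mutant cannot avoid — a
much stronger statement than production *at* optimal growth.

Assumptions worth keeping in mind:

* steady state and fixed bounds — no kinetics, no regulation;
* knockouts act on reactions (columns of $S$), not genes; mapping through
  gene–protein–reaction rules is out of scope;
* the growth floor ($g_{\min}$) represents viability, defaulting to 10% of
  wild-type maximal growth, and is enforced *inside* the inner problem, so
  designs that cannot sustain it are infeasible rather than merely
  penalised — this is what makes infeasible designs generate Benders
  feasibility cuts during the search.

## From bilevel to a single-level MILP

The knockout bounds $lb_j(1-y_j) \le v_j \le ub_j(1-y_j)$ couple the binary
and continuous levels disjunctively; the classical big-M treatment of this
coupling is the main source of numerical trouble in genome-scale MILPs.
Instead, the inner objective is augmented with Lagrangian penalties
$\sum_j M_j\,|v_j|\,y_j$, with $M_j$ drawn once per run, uniformly from
$[90, 110]$ (seeded, default 2020). Values near 100 dominate any
achievable gain in target flux on the networks considered while keeping
coefficients within two orders of magnitude of the stoichiometry.
$|v_j|$ is linearised through magnitude variables $u_j \ge \pm v_j$ capped
by $U_j = \max(|lb_j|, |ub_j|)$; reversible reactions therefore keep their
signed bounds and are never split.

LP duality applied to the penalised inner LP gives the single-level MILP
built by `buildSingleLevelMILP()`: variables $x = (v, u, \lambda, \alpha,
\beta, \gamma, \rho, \sigma, \delta)$ and binaries $y$, with

1. inner primal feasibility,
2. inner dual feasibility, whose $u$-stationarity rows are relaxed by
   $M_j y_j$,
3. a strong-duality equality pinning $c_P'v$ to the dual objective,
4. coupling rows $u_j + U_j y_j \le U_j$, which force $u_j = v_j = 0$ for
   knocked-out reactions and thereby cancel the bilinear $M_j y_j u_j$
   term that would otherwise appear in the strong-duality row,
5. the budget $\sum_j y_j \le K$.

The budget is $\le K$ (not the strict inequality sometimes written), since
$K$ is the *maximum allowable* number of knockouts and $K$-knockout optima
are meaningful. Block-matrix transcriptions of this reformulation are
easy to get subtly wrong, so the construction is validated behaviourally
rather than trusted:
the package's test suite checks, on every fixture, that the MILP optimum
equals an exhaustive enumeration of the max–min problem, that knocked
fluxes vanish ($|v_j| \le 10^{-6}$ when $y_j = 1$), and that the
strong-duality residual is below $10^{-6}$.

Both inequality blocks for the knockouts are kept deliberately: the
coupling rows make the primal side exact regardless of penalty size, while
the penalties keep the slave dual bounded and the cuts well-scaled.

## The hybrid Benders loop

`runHBA()` decomposes the MILP into a binary master over $(y, z)$ and a
continuous slave at fixed $\bar y$. A bounded slave returns an optimality
cut $z \le (b - By)'\pi^o$; an infeasible slave returns a feasibility cut
$(b - By)'\pi^f \ge 0$ from a dual ray, recovered from the phase-1
(elastic) LP's duals. Three acceleration devices:

* **Pareto-optimal cuts.** The slave right-hand side is perturbed to
  $(b - B\bar y) + \mu(b - B\hat y)$, where $\hat y$ is a core point in the
  relative interior of the design hull, updated by averaging,
  $\hat y \leftarrow \tfrac12(\hat y + \bar y)$, at every feasible design.
  $\mu = 10^{-8}$: small enough that the perturbation's contribution (which
  is removed from the reported slave value) is below reporting precision,
  large enough to select a non-dominated dual vertex. The initial core
  point $\hat y_j = \min(0.5,\, K/(|\bar J| + 1))$ is interior by
  construction. Optionally the slave is re-solved at $\mu = 0$
  (`resolveUnperturbed`), off by default since the removed-perturbation
  value is within $\mu\,\lVert b - B\hat y\rVert$ of exact.
* **Local branching.** The master is restricted to the Hamming ball
  $\Delta_H(y, y') \le r - 1$ around an incumbent reference $y'$
  (initially the wild type, $r_0 = 3$). An empty ball is excluded by the
  reverse inequality $\Delta_H \ge r$ and the radius grows by one, so the
  next region is exactly the unexplored shell; a ball whose master bound
  has dropped to the incumbent slave value is likewise certified and
  reversed. When the master value at $\bar y$ is no better than its slave
  value, the ball is re-centred on $\bar y$. On integer variables the
  strict inequalities sometimes written for these rules are ambiguous; the
  $\le r-1$ / $\ge r$ pair used here is the standard integer form and is
  the one under which the explored/unexplored regions partition cleanly.
* **Early master termination.** The master stops at the absolute gap
  $1 + 300/(\sqrt{iter} + 1)$ (flux units): crude incumbents suffice for
  early cuts. A relative-gap reading would exceed 100% and be meaningless,
  so the schedule is passed to the engine as gap divided by the $z$ cap.

The surrogate $z$ is capped by the theoretical maximum production (TMP),
a valid bound that replaces an unbounded initial master. The global upper
bound $\bar z$ is only tightened from master bounds obtained when no
interior ball is active — i.e. when the current region plus the certified
exclusions cover the unexplored design space — and is floored at the
incumbent $\underline z$; this keeps $\bar z$ monotone non-increasing and
$\underline z \le \bar z$ throughout, which the tests assert on every run.
Termination: bound closure ($\bar z - \underline z \le 10^{-4}$), an
iteration cap (default 10 000) or a wall-clock budget (default 3600 s).

Every feasible design whose slave value reaches `thresholdFraction × TMP`
enters the pool (default threshold 0: keep everything feasible, filter
later with `filterPool()`). Designs are deduplicated and ordered by
guaranteed minimum production, ties broken lexicographically; a visited
cache prevents duplicate slave solves and duplicate cuts.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `K` | 5 | count | knockout budget |
| `minGrowthFraction` | 0.1 | – | growth floor as fraction of wild type |
| `nC` | 100 (off) | carbons | candidate carbon cutoff |
| `mRange` | [90, 110] | – | Lagrangian penalty interval |
| `penaltySeed` | 2020 | – | penalty draw seed |
| `mu` | 1e-8 | – | Pareto perturbation weight |
| `r0` | 3 | count | initial branching radius |
| `tolClosure` | 1e-4 | flux | bound-closure tolerance |
| `thresholdFraction` | 0 | – | pool admission threshold (× TMP) |

Numerical tolerances: LP feasibility $10^{-9}$ (the engine's default
regime), zero-flux and coupling decisions $10^{-6}$. Tie-breaking between
alternate LP optima is solver-dependent; only objective values are
contract-bearing, never flux vectors.

## Preprocessing and candidate selection

Model reduction removes blocked reactions (flux range $\{0\}$, by
per-reaction flux variability) to a fixed point and compresses linear
chains — an internal metabolite with exactly one producer and one
consumer — into pseudo-reactions with flux-scaled intersected bounds,
keeping a mapping back to original ids. Only irreversible pairs are
merged, and the biomass reaction and all exchanges are protected, so sinks
are never folded into the biomass or the target export. Both steps
provably preserve the growth optimum, and the tests re-check this on
every fixture.

Candidate selection excludes the biomass and target reactions, all
exchanges (the oxygen exchange is *kept* by default — anaerobic-switch
designs are among the most productive and knocking the oxygen uptake must
remain available), reactions without gene rules, essential reactions
(single-deletion FBA below the same growth floor used in search), user
exclusions, and — optionally — reactions touching any metabolite with more
than $n_c$ carbons, the classical search-space reduction. $n_c \ge 100$
disables the carbon filter, which is the default: the filter can exclude
the true optimum, and the Benders machinery makes the full candidate set
affordable. Every rule's removal count is logged so candidate-set sizes
can be compared across settings.

## What the synthetic fixtures do and do not show

`makeToyNetwork()` generates the study networks. `"toy5"` is the minimal
network with one uncoupled and one coupled route; `"random_branched"`
draws `nBranches` parallel two-step substrate→biomass routes, a fraction
of which co-produce the target, with stoichiometric coefficients from
{1, 2} so that every LP optimum stays hand-checkable. Uptake is capped at
10 mmol/gDW/h, internal bounds at 1000. These fixtures exercise every
code path — alternate optima, infeasible designs (feasibility cuts),
coupled and uncoupled routes, tie handling — and they are small enough
for exhaustive enumeration, which is what makes the oracle-equivalence
acceptance checks possible (toy5 plus dozens of generated fixtures with
up to ~10 candidates and $K \le 3$; the test suite and acceptance script
state their exact grids).

They do **not** emulate genome-scale features: thousands of reactions,
highly variable stoichiometric coefficients (the regime where big-M
formulations fail), cofactor cycles, compartments, or candidate sets in
the hundreds. Passing tests therefore certify the *algorithms'
correctness*, not genome-scale runtimes; applying the package to a real
model (e.g. an *E. coli* reconstruction with a succinate or ethanol
target) uses exactly the same code path via `loadModel()` but is an
hours-scale computation dominated by the MILP engine.

## Degenerate inputs and edge cases

* `K = 0` reduces to the wild-type inner minimum; the empty design is a
  legal pool member.
* A design infeasible at the growth floor is *skipped* by the enumeration
  oracle, *excluded* by a feasibility cut in the Benders loop, and an
  error in `evaluateRecord()`.
* A model whose wild type cannot reach the floor is rejected up front.
* Zero-growth models still envelope correctly (a single grid point at 0).
* An empty candidate set after filtering raises an error advising a larger
  $n_c$ rather than returning an empty run.

## Known limitations

* Gene-level mapping (GPR logic), MOMA-style re-ranking and heterologous
  pathway construction are out of scope; users supply augmented models.
* The solution pool is search-order dependent (as in any in-search pool);
  only its best value and the per-record evaluations are contracts.
* Bound closure proves optimality only up to `tolClosure`; like all
  Benders schemes, late-stage convergence can be slow on hard instances,
  in which case the time budget returns the incumbent pool.
* The LP/MILP engine is exercised through a minimal solver contract
  (status, primal, duals, Farkas certificate via phase-1); swapping in
  another engine requires only that contract.
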