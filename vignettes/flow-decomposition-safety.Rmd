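---
title: "Safe paths for minimum flow decompositions: models, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safe paths for minimum flow decompositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowsafety)
```

## The model

A flow network here is a DAG `G = (V, E)` with a unique source `s`, a unique
sink `t`, and a positive integer flow `f_uv` on every edge, conserved at every
internal node. In the transcriptomics reading, nodes are exons, edges are
splice junctions, and `f` is the (perfect) read abundance. A *flow
decomposition* (FD) into `k` paths is a multiset of `s`-`t` paths `P_i` with
integer weights `w_i ≥ 1` whose superposition equals `f` edge-wise; a
*minimum* FD (MFD) minimizes `k`. Minimizing `k` is the parsimony assumption
under which the decomposition paths are interpreted as transcripts; the
problem is NP-hard, which is why an integer program sits at the core of this
package.

A path `P` is *safe* when every MFD has some solution path containing `P` as a
contiguous subpath, and *maximal safe* when no proper extension is safe. Safe
paths are the fragments common to all parsimonious explanations of the data
— the multiassembly analogue of contigs.

### The k-path integer program

`buildFdModel()` uses, per path slot `i` and edge `(u,v)`, a binary indicator
`x_uv^i` subject to per-node balance constraints so that each slot's selected
edges form one `s`-`t` path (on a DAG a unit of integral flow cannot
recirculate, so balance suffices). Integer weights `w_i ∈ [1, W]` and product
variables `π_uv^i ∈ [0, W]` linearize the bilinear superposition requirement
`Σ_i x_uv^i · w_i = f_uv` through the standard big-M triple

```
π ≤ W·x,    π ≤ w,    π ≥ w − W·(1 − x),
```

with `W = max f_uv`: no path can carry more weight than the flow of any edge
it uses, so this bound is tight enough to keep the relaxation useful and the
model exact. Subpath constraints `R_1..R_ℓ` (known transcript fragments, e.g.
from long reads) add binaries `r_ij` with
`Σ_{(u,v)∈R_j} x_uv^i ≥ |R_j|·r_ij` (|R_j| counted in edges — a single-edge
constraint degenerates to `x ≥ r`) and `Σ_i r_ij ≥ 1`.

`findMinimumK()` searches `k` linearly upward from
`max(outdeg(s), indeg(t))`; each solution path consumes one out-edge of `s`
and one in-edge of `t` and all must be covered, so the bound never overshoots.
Linear search is deliberate: in splice graphs `k*` is small and infeasibility
certificates at small `k` are cheap, so galloping search would buy nothing.

### The group safety test

For a set of candidate paths, one solve decides as much as possible
(`groupTest()`): each tested path `P = (v_1 … v_ℓ)` gets a binary avoidance
indicator `γ_P` constrained, for every slot,

```
x_{v1v2}^i + … + x_{v(ℓ−1)vℓ}^i ≤ (ℓ−1) − γ_P,
```

and the objective maximizes `Σ γ_P`. Because solution paths never repeat
nodes, a slot contains `P` exactly when it uses all `ℓ−1` of its edges, so
`γ_P = 1` is feasible only if some MFD avoids `P` — such paths are unsafe —
while an optimum of 0 proves every tested path safe. `getSafe()` iterates:
report the avoided set as unsafe, re-test the remainder; a set with `u` unsafe
members is resolved in at most `u + 1` solves, and in exactly one when
everything is safe. Safety is always evaluated at the fixed minimum
cardinality `k*`; the avoidance layer never changes `k`. Ties among optima of
the avoidance objective are solver-dependent and harmless: any maximizer
certifies its avoided set.

### Outer algorithms

Every maximal safe path is a window of a solution path of *any* fixed MFD, so
both outer algorithms scan windows of one decomposition returned by
`findMinimumK()`:

* `trimMaximalSafe()` (default) keeps a *trimming core* of windows, initially
  the full solution paths, with the invariant that every unreported maximal
  safe path lies inside some core window and no core window sits inside an
  already-reported safe path. Each round resolves the whole core with a single
  recursive group test; safe windows are maximal safe by the invariant, and
  each unsafe window spawns its two one-node trims (left, right), minus
  duplicates, sub-edge windows, and windows contained in already-reported safe
  paths. Single-edge windows have positive excess flow, so the recursion
  terminates without the ILP.
* `twoPointerMaximalSafe()` slides left/right pointers per solution path,
  testing one window at a time; since subpaths of safe paths are safe, the
  maximal right end is monotone in the left end and the scan emits exactly the
  per-path maximal windows. It is the natural baseline: the trimming algorithm
  exists to cut its one-window-per-solve cost, and the suite asserts the
  direction of that saving (trimming never uses more solves over the benchmark
  suite; the observed totals are logged by the tests).

Before any solve, `excessFlowPrefilter()` removes windows whose *excess flow*
— flow on the first edge minus all flow leaving the window's internal nodes
off-path — is positive; positivity characterizes safety for **all** FDs (of
any size), which implies safety for MFDs. This test is linear-time and
resolves the bulk of short windows.

Reports are canonicalized (`canonicalizePaths()`): duplicates and paths
contained in another reported path are dropped and the rest sorted
lexicographically, so the output is a deterministic antichain.

## Contraction: what it can and cannot carry

`contractYtoV()` merges `(u,v)` when `v` has in-degree one or `u` out-degree
one (never eliminating `s` or `t`), so each contracted edge represents an
*extended unitig*: a path whose interior is a block of in-degree-one nodes
followed by a block of out-degree-one nodes. Any decomposition path using the
edge between the two blocks is forced through the whole unitig — that is what
makes unitigs safe for every FD. Two design points deserve a note, both found
the hard way against the enumeration oracle:

* **Merge order matters.** Unrestricted merging can build chains whose
  interior has out-branching collected *before* in-branching; those are not
  extended unitigs and not safe. Merges are therefore restricted to preserve
  the `[in-degree-1][out-degree-1]` interior structure (the implementation
  tracks the two block lengths per edge). The suite asserts that every
  contracted edge has positive excess flow.
* **Safety is computed at original-node granularity.** A maximal safe path
  may *end inside* an extended unitig, at the boundary between its
  in-branching prefix and out-branching suffix; windows made of whole
  contracted edges cannot express such a path, and post-extending expanded
  windows through forced nodes is not sufficient either (different MFDs can
  cover such a path via different parallel contracted edges). The pipeline
  therefore uses contraction only for what it soundly provides: source-to-sink
  contracted edges are members of every MFD, so `findAllMaximalSafeMFD()`
  reports them as maximal safe immediately and *peels* their flow off the
  graph; for a funnel (a graph whose decomposition is unique up to splitting
  weights) this resolves the instance with zero ILP calls. The outer
  algorithms then run on the residual graph in original coordinates. The
  `contract = FALSE` switch disables the peeling, and the suite checks that
  `k*` and the safe set are identical either way.

When subpath constraints are present the peeling is skipped too, since
constraint paths may overlap the peeled unitigs; correctness is unaffected
because peeling is an optimization only.

### Time budget

Each graph gets a wall-clock budget (default 120 s, covering the `k*` search
and all group tests; each solve receives the remaining budget). On exhaustion
all partial MFD-safety results are discarded and the safe-for-all-FDs baseline
(`safePathsAllFDs()`, excess-flow only, no ILP) is returned with
`mode = "all_fd_fallback"` — all-or-nothing per graph, so a report is always
entirely one notion of safety.

## The solver

No MILP library is part of this package's dependency stack, so the integer
programs are solved by a bundled branch-and-bound over a dense two-phase
primal simplex (C++): Dantzig pricing with a switch to Bland's rule after an
iteration budget (guaranteeing termination), bounds handled by variable
elimination (fixed variables) plus explicit upper-bound rows, depth-first
branching on the most fractional integer variable exploring the nearer side
first, and integral-objective bound rounding. The model coefficients are small
integers and the problems a few hundred variables, well inside what a dense
tableau handles; feasibility tolerance is 1e-7 and integrality tolerance
1e-6. Everything is single-threaded and deterministic: two runs on one model
return the same assignment. The solver is validated in the test suite against
lattice enumeration on random all-integer models, and indirectly by the
oracle-equivalence suites, which exercise thousands of solves whose outcomes
brute force confirms. The backend is selected by name
(`options(flowsafety.solver = )`), keeping core logic backend-agnostic.

## The synthetic generator and what the tests do (and do not) show

`generateInstance()` emulates the benchmark construction: a random DAG
skeleton on a topological order (every node reachable from node 0 and
co-reachable from node n−1, plus extra random forward edges), `t` random
source-to-sink transcript walks, integer abundances, and edge flows defined as
the exact superposition — so flow conservation holds by construction and the
transcripts are a ground-truth FD. Funnels are rejected and resampled when
`requireNontrivial = TRUE`, mirroring how trivial instances are filtered from
the community benchmarks. Abundances default to uniform integers 1..100 — a
simple, documented choice; real transcript abundances are heavy-tailed, and a
Zipf-flavoured sampler can be passed via `weightSampler` when that matters.
`makeSubpathConstraints()` draws ⌊t/2⌋ transcripts and takes each one's
shortest prefix containing three junctions (internal nodes with in- or
out-degree ≥ 2 by default; out-degree only via `junctionRule = "out"` — the
notion of a "nontrivial junction" admits both readings, so both are
implemented), falling back to the full transcript when it has fewer than
three.

The oracle suites run on instances small enough for exhaustive enumeration
(≤ 8 nodes, total source out-flow ≤ 8): `enumerateAllFDs()` lists every
weighted-path multiset superposing to `f`, and `bruteForceSafe()` derives
safety by definition. Within that scale the pipeline is verified *exactly* —
equality of safe sets, minimality of `k`, agreement of the two outer
algorithms, contraction invariance, and the excess-flow characterization, on
200 seeded instances plus the hand-built gadgets. What those tests do **not**
show: behaviour on real splice graphs (hundreds of nodes, heavy-tailed
abundances, imperfect flows), where ground truth is not enumerable and the
generator's idealisations (perfect superposition, uniform abundances, exact
node alignment) do not hold. On such data the correct-by-construction
guarantees still apply to the *safety* semantics, but quality against the true
transcripts depends on whether the truth is a minimum decomposition — the
known failure mode of the parsimony assumption for complex graphs built from
many transcripts.

## Metrics

`evaluateGraph()` follows the standard multiassembly scoring, with lengths in
nodes (exons): *weighted precision* = total length of correctly reported
paths / total length of reported paths (a path is correct iff it is a
contiguous subpath of some truth path); *maximum coverage* = per truth path,
the longest segment shared with any reported path divided by the truth path's
length, averaged over truth paths; *F-score* = harmonic mean of the two (0
when both are 0). Two corners the definitions leave open are pinned down
explicitly: an empty reported set scores precision 1 (there is no incorrect
length) with a warning and a flag column, and because "average weighted
precision over all reported paths" and the length-ratio formula disagree when
path lengths vary, the length-ratio is the default with the per-path mean
available as `method = "mean"`. `aggregateEvaluations()` averages per-graph
metrics, overall and stratified by the number of ground-truth paths
(`t ≤ 10`, `t ≤ 15`, ... matching the usual table layout).

## Numerical and degenerate-input choices

* Graphs must have exactly one source and sink; multi-endpoint inputs are
  rejected unless `augment = TRUE` adds a super-source/sink carrying each
  endpoint's imbalance.
* Paths are node sequences with 0-based inclusive windows internally; all
  candidate bookkeeping is by edge-index sequences so parallel edges of
  contracted multigraphs stay unambiguous.
* Deterministic ordering everywhere: sorted contraction scans, lexicographic
  candidate and report ordering, seeded generators that restore the caller's
  RNG state. Safe *sets* are solver-independent; determinism makes the whole
  artifact reproducible run to run.
* A time budget of 0 is honoured before the first solve (`status "timeout"`),
  so the fallback path is testable without waiting.
* Duplicate tested paths are merged (with a warning) before the avoidance
  layer is built — identical indicators would distort the objective.

## Known limitations

* Cyclic graphs, trails/walks (repeated edges or nodes), and fractional
  weights are out of scope; so is safety over non-minimum FDs of bounded size
  ("at most k′ paths"), though the model layer would admit it by swapping the
  cardinality handling.
* The bundled solver is meant for splice-graph-sized models (hundreds of
  variables); it is not a general-purpose MILP code, and very large graphs
  should expect the per-graph budget to trigger the all-FD fallback.
* The bottom-up (extend-safe-prefixes) outer algorithm is not implemented;
  the trimming-core and two-pointer algorithms cover the produced-set
  semantics, and their agreement is tested.
* Evaluation is exact node alignment only; genomic-coordinate scoring is not
  implemented.
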