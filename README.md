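# flowsafety

Safe paths for minimum flow decompositions of splice graphs.

## The problem

RNA transcript assembly (and multiassembly in general) is routinely modelled
as **flow decomposition**: reads from a mixed sample are aligned and summarised
into a splice graph — a DAG whose nodes are exons and whose edges are splice
junctions — with a read-abundance flow `f` on the edges. A *flow
decomposition* (FD) is a set of source-to-sink paths `P_1, …, P_k` with
positive integer weights `w_1, …, w_k` whose superposition reproduces the
flow on every edge:

```
Σ_{i : (u,v) ∈ P_i} w_i = f_uv        for every edge (u,v).
```

A *minimum* flow decomposition (MFD) uses the smallest possible `k`; it is the
standard parsimony model for recovering transcripts, and it is NP-hard. Since
many decompositions usually attain the minimum, no single one can be trusted.
The honest output is the set of **safe paths**: paths contained (contiguously)
in some path of *every* minimum decomposition. A *maximal* safe path is one
that cannot be extended without losing that guarantee. These are the transcript
fragments that every parsimonious explanation of the data must contain.

`flowsafety` computes **all maximal safe paths for MFDs** with an integer
linear programming (ILP) safety test:

* the k-path MFD model itself — binary edge indicators `x_uv^i` with per-node
  balance constraints, integer path weights, linearized superposition, and
  optional *subpath constraints* (paths that must appear inside a solution
  path, e.g. from long reads);
* the **group safety test**: one extra binary indicator `γ_P` per tested path
  `P = (v_1 … v_ℓ)` with, for every path slot `i`,

  ```
  x_{v1v2}^i + … + x_{v(ℓ-1)vℓ}^i ≤ (ℓ−1) − γ_P
  ```

  and objective `maximize Σ_P γ_P`. Avoided paths (`γ_P = 1`) are unsafe; an
  optimum of 0 certifies every tested path safe. A recursive procedure
  (`getSafe`) resolves a whole set with at most one ILP call per unsafe path,
  plus one;
* two outer algorithms that enumerate all maximal safe paths from the windows
  of one minimum decomposition: a group-testing **trimming-core** algorithm
  (default) and a singleton **two-pointer** scan;
* the practical shortcuts: Y-to-V contraction (extended unitigs), peeling of
  source-to-sink unitigs, funnel short-circuit, and the linear-time
  **excess-flow** test (positive excess flow ⇒ safe for *all* FDs, no ILP
  needed);
* baselines (`extendedUnitigs`, `safePathsAllFDs`), a synthetic splice-graph
  generator with known ground truth, brute-force enumeration oracles, and the
  multiassembly quality metrics (weighted precision, maximum coverage,
  F-score).

The integer programs are solved by a small deterministic branch-and-bound
solver over a two-phase simplex, bundled as C++ code.

## Worked example

A 6-node graph whose minimum decomposition is unique although many larger
decompositions exist:

```r
library(flowsafety)
inst <- gadget("g4")
net  <- instanceNetwork(inst)
net
#> FlowNetwork 'g4': 6 nodes, 7 edges, source=0, sink=5
#>   0 -> 1 : 1
#>   0 -> 2 : 2
#>   1 -> 2 : 1
#>   2 -> 3 : 2
#>   2 -> 4 : 1
#>   3 -> 5 : 2
#>   4 -> 5 : 1

findMinimumK(net)$decomposition
#> WeightedDecomposition: 2 weighted paths
#>   w=1  0 1 2 4 5
#>   w=2  0 2 3 5

rep <- findAllMaximalSafeMFD(net)
rep
#> SafetyReport 'g4' [mode=mfd_safe]: 2 maximal safe paths, 2 ILP calls
#>   [ilp] 0 1 2 4 5
#>   [excess_flow] 0 2 3 5
```

Both full transcripts are safe for the minimum decomposition: the MFD is
unique, so its two paths appear in "every" MFD. The classical safe-for-all-FDs
baseline is strictly weaker here — a size-3 decomposition avoids the middle of
the first transcript, so it breaks into two fragments:

```r
safePaths(safePathsAllFDs(net))
#> [[1]] 0 1 2
#> [[2]] 0 2 3 5
#> [[3]] 2 4 5
```

Evaluating the safe paths against the instance's ground-truth transcripts
(lengths in nodes/exons):

```r
evaluateGraph(rep, transcriptPaths(inst))
#>   graphId t nReported nCorrect wtPrecision maxCoverage fScore emptyReported
#> 1      g4 2         2        2           1           1      1         FALSE
```

`generateInstance()` produces random splice-graph instances with known
transcripts (perfect superposition, funnels filtered), `enumerateAllFDs()` and
`bruteForceSafe()` are enumeration oracles for small instances, and the
`exec/flowsafety` script exposes `safety`, `mfd`, `simulate` and `eval`
subcommands for shell use.

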