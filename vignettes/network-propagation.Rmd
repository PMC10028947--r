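---
title: "Methods: network propagation, bootstrapped nulls and in-silico repression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network propagation, bootstrapped nulls and in-silico repression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppinet)
```

ppinet is a toolkit for the three recurring steps of an interactomic
analysis: obtaining a protein–protein interaction (PPI) network, reducing it
to a phenotype-specific subnetwork, and ranking its nodes to nominate
candidate drug targets. This vignette is the package's account of the
underlying methods — the models, their assumptions, the tunable parameters,
and the design choices made where the design was genuinely open.

## The graph model

A PPI network is represented as a simple undirected igraph object: vertices
are protein or gene identifiers, edges are binary interactions. On ingest
(`build_graph()`, and the StringDB/BioGRID parsers built on it) self-loops
are dropped and duplicate edges — including the same pair in the opposite
orientation — are collapsed, keeping the maximum confidence when a
confidence column is present. Edge confidence (StringDB's `combined_score`,
an integer on a 0–1000 scale) is used *only* to filter edges at parse time
(default threshold 400, the conventional medium-confidence cutoff, fully
overridable); it never reweights the random walk. The walk operates on pure
topology, the simplest reading of an adjacency-matrix formulation, and a
weighted walk is deliberately out of scope.

`to_transition_matrix()` converts a graph into a sparse column-stochastic
matrix `W`: column *j* places `1/deg(j)` on each neighbour of *j*. The
row/column order is lexicographic in the node identifiers and fixed at
construction, so every downstream computation is deterministic across runs.
Isolated nodes get all-zero columns: an isolated node has no in-edges in an
undirected graph, so no walk mass can reach it, and the only way mass could
rest there is if it were a seed — which the walk forbids. This avoids
inventing teleportation semantics for nodes the model cannot reach.

## Random walk with restarts

Signal is propagated from a set of seed proteins by the iteration

$$p^{(t+1)} = (1-\gamma)\,W p^{(t)} + \gamma\, r,$$

with restart vector $r$ uniform over the seeds, initial state $p^{(0)} = r$,
and restart probability $\gamma$. The fixed point assigns every node an
*affinity score*: the stationary probability that a walker anchored at the
seeds visits that node. Iteration stops when the L1 change in one step falls
below `eps`, or after `tmax` iterations (the `converged` flag records
which).

Parameter choices, all exposed through `rwr_params()`:

* `gamma = 0.6` — the restart probability. Larger values keep mass near the
  seeds; smaller values diffuse further. With $|S|$ seeds, every seed
  retains at least $\gamma/|S|$ of the mass (the $k{=}0$ term of the Neumann
  series), a bound the test suite checks.
* `eps = 1e-10` (L1) — the L1 norm matches the probability-mass semantics of
  $p$; with contraction factor $1-\gamma$, convergence is geometric and
  ~40–80 iterations suffice at these tolerances.
* `tmax = 200` — a generous cap given the geometric rate.
* $p^{(0)} = r$ — makes the $\gamma = 1$ limit exact after one iteration
  (the walk degenerates to the restart vector).

Because `W` is column-stochastic on non-isolated columns and seeds must be
non-isolated, $\|p\|_1 = 1$ holds at every iteration exactly (up to
floating-point error); the suite asserts this and cross-checks the iterate
against `solve_rwr_exact()`, a dense solve of
$p = \gamma (I - (1-\gamma) W)^{-1} r$ that serves as an independent oracle
on graphs up to 2000 nodes.

## The degree-matched bootstrap null

An affinity score alone does not separate "functionally close to the seeds"
from "close to everything" — high-degree hubs score well against any seed
set. `compute_crosstalk()` therefore compares each node's observed affinity
with a bootstrapped null: `n_bootstrap` random walks whose seed sets replace
each observed seed by a non-seed node drawn uniformly from the same
*logarithmic degree bin* (`floor(log2(degree))`, so a seed of degree 100
matches candidates of degree 64–127), without replacement within a set.
Exact-degree matching starves bins in sparse graphs; log-bins are the common
practice. All null walks reuse the observed transition matrix unchanged.

Per node, the empirical p-value uses the add-one permutation correction

$$p(v) = \frac{1 + \#\{b : \text{null}_b(v) \ge \text{observed}(v)\}}{1 + B},$$

with ties counting as exceedances; p-values are therefore never exactly
zero — a node beating all $B$ draws reports $1/(B+1)$. After adjustment
(Benjamini–Hochberg by default; Holm and Bonferroni available via
`stats::p.adjust`), nodes with adjusted p strictly below
`significance_level` (default 0.05) are *retained*, and the induced
subgraph on the retained set is returned alongside the ranked table.
Defaults `n_bootstrap = 1000` and BH are conventional choices. Each
bootstrap replicate *b* derives its RNG stream from `(rng_seed, b)`, so
results are reproducible and independent of any execution order.

Two structural caveats, verified by the calibration test: the null draws
each node's affinity against *its own* per-node null distribution (the
conservative reading of comparing scores to "the null distribution"), and
observed seeds are excluded from the candidate pools, so the seeds
themselves always come out at $p = 1/(B+1)$ — significance of the seed rows
is a statement about the scheme, not about the data. Non-seed nodes are
well calibrated: with seed sets drawn from the same degree-matched scheme,
the fraction of nodes at $p \le 0.05$ stays within the binomial band around
0.05 (the acceptance suite measures this on a 200-node preferential-
attachment graph with $B = 99$ over 50 replicates).

## Node scoring and graph filtration

Four scoring methods ship with the package; each returns a named numeric
vector usable with `gfilter()`:

* `degree_score()` — neighbour counts.
* `betweenness_score()` — unnormalised betweenness over unweighted shortest
  paths, $g(v) = \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$, counting
  each unordered pair once (the igraph convention). The suite validates it
  against an exhaustive BFS path-counting oracle on small graphs.
* `network_potential()` — the thermodynamic score
  $G_i = C_i \ln\!\big(C_i / (C_i + \sum_{j \in N(i)} C_j)\big)$, where
  $C_i$ is node *i*'s positive expression weight and the sum runs over its
  neighbours. The log argument lies in $(0,1]$, so $G_i \le 0$, an isolated
  node scores exactly 0, and scaling all weights by $k$ scales every score
  by $k$ (the ratio inside the log is scale-invariant). Nodes with missing
  or non-positive weights are an error, not silently zero-filled: zero is
  meaningless on a log scale, so unweighted nodes must be removed first
  (`gfilter_by_value()` does exactly this).
* affinity from `compute_crosstalk()` — the RWR route to filtration.

`gfilter()` keeps the top-*n* (or bottom-*n*) nodes by score and induces the
subgraph, breaking ties by node identifier so filtration is deterministic
and idempotent; `gfilter_by_value()` ranks by a user-supplied named vector
(e.g. log-scale expression), excludes unvalued nodes, and attaches the
value as the `weight` vertex attribute so the result feeds straight into
`network_potential()`.

Expression input (`load_expression()`) applies $\log_2(E + 1)$ by default.
The pseudocount is a deliberate deviation from a bare $\log_2 E$: zero
counts are common in RNA-seq-derived vectors and would otherwise produce
$-\infty$; the flag `log2_transform = FALSE` gives the untransformed
values, and identifiers that are non-positive after transformation are
reported in the `"flagged"` attribute.

## In-silico repression

`node_repression()` ranks candidate targets by perturbation: how much does
the total network state $S = \sum_v s_v$ change when a node is deleted?
With network potential as the state function, deleting node *i* only alters
the neighbourhood sums of *i*'s direct neighbours, so the incremental
recomputation touches exactly $N(i)$ — the package recomputes
$s^{(i)}_v = C_v \ln\!\big(C_v/(C_v + \sum_{j \in N(v)} C_j - C_i)\big)$
for $v \in N(i)$ and nothing else. The result is a sparse nodes × targets
matrix whose entry $(j, i)$ is $s_j - s^{(i)}_j$, with the removed node's
own score $s_i$ on the diagonal (present in $S$, absent from $S_i$); each
column sums *exactly* to $\Delta S_i = S - S_i$, and the suite checks the
incremental result against a full-recompute oracle at 1e-12 on hundreds of
target columns. `rank_targets()` orders by $|\Delta S|$ (potentials are
negative, so removals typically drive $\Delta S$ negative; magnitude
ranking surfaces the most critical nodes) and always reports the signed
value.

Only network potential ships as a state function; the `state_function`
argument is the seam for future per-node state functions with their own
affected-set logic.

### The rewired-graph null

Hub effects confound repression rankings just as they confound affinities.
`compute_null_dnp()` builds a topology null by re-scoring every target on
`n_rewires` degree-preserving randomisations of the graph
(`rewire_preserving_degrees()`: repeated double-edge swaps that reject
self-loops and multi-edges, `ceiling(swap_multiplier * |E|)` attempts with
`swap_multiplier = 10`, a standard burn-in for degree-sequence
randomisation). Expression weights stay attached to their node identities —
only topology is randomised. Per target,
$p = (1 + \#\{|\Delta S_{\text{null}}| \ge |\Delta S_{\text{obs}}|\}) / (1 + n_{\text{rewires}})$.
On a regular graph with equal weights, rewiring cannot change any
neighbourhood sum, so every null draw ties the observation and all p-values
are 1 — a degenerate case the suite uses as a sanity check. Note that
graphs admitting no valid swap (fewer than two edges, or rigid cases like a
triangle) come back unchanged, making the null uninformative there.

## What the synthetic fixtures emulate — and what they do not

`make_graph()` generates seeded Erdős–Rényi, Barabási–Albert (the
heavy-tailed degree distribution typical of PPI networks), ring, star and
two-clique graphs; `make_expression()` draws strictly positive lognormal
weights (`meanlog = 2`, `sdlog = 1`), emulating the right-skewed,
positive-support shape of linear-scale expression values.
`write_fixture_files()` emits the exact StringDB/BioGRID/expression
dialects the parsers consume, so the whole pipeline — parsing included —
runs without downloads.

These fixtures exercise correctness, determinism and calibration. They do
*not* reproduce the correlation between expression and connectivity, the
modular community structure, or the curation biases of a real interactome,
and edge-list dialects cannot represent isolated vertices. Passing tests
demonstrate that the algorithms compute what they claim on graphs of known
structure — not that any particular biological ranking is correct. Test and
acceptance problem sizes (graphs of 2–200 nodes, bootstrap sizes 9–99 in
the property checks) were chosen so the distributional claims are sharp at
desk scale; the algorithms themselves are sparse end-to-end and the
defaults (`n_bootstrap = 1000`) are intended for genome-scale graphs.

## Numerical and degenerate-case conventions

* Node order is lexicographic everywhere a matrix or file is produced;
  score and ranking ties break by node identifier ascending.
* Walk convergence uses the L1 norm; the dense oracle guards itself to
  2000 nodes.
* A neighbour whose only neighbour is the removed target lands on
  $\ln(1) = 0$ exactly (its reduced neighbourhood sum is exactly zero).
* Empty retained sets from `compute_crosstalk()` warn and return an empty
  table plus an empty subgraph rather than erroring.
* Caches are gzipped edge-list TSVs — portable and inspectable; a corrupt
  cache is an error naming the file, never a silent refetch.

## Known limitations

* Walks are unweighted; confidence scores gate ingest only.
* One state function (network potential) for repression.
* The degree-matched null cannot re-draw an observed seed, so seed rows'
  p-values are floor values by construction.
* Hubs in sparsely populated degree bins have few null candidates; the
  binning errors loudly when a bin is empty rather than silently widening.
* No identifier mapping between symbol namespaces; inputs must share one
  namespace.
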