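---
title: "Detecting protein complexes with a genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes with a genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gacomplex)
```

## The problem

Protein–protein interaction (PPI) networks are modular: protein complexes
appear as locally dense subgraphs, but they are rarely cliques, their
densities vary across the network, and a protein can belong to more than one
complex. gacomplex treats complex prediction as an optimization over
*overlapping clusterings* of the network and searches that space with a
mutation-only genetic algorithm (GA), seeded either at random or from a
recursive spectral bisection of the graph.

## The model and its objectives

A candidate solution is a list of $k$ clusters $\{C_1,\dots,C_k\}$ over the
$N$ network proteins; a protein may appear in several clusters. For cluster
$C_k$ write $W_{kk}$ for its internal edge count, $W_{ki}$ for the number of
edges with exactly one endpoint in $C_k$ (its boundary), and
$A_k = |C_k|(|C_k|-1)/2$ for its maximum possible internal edge count. The
default fitness is the density cut

$$\mathrm{JD}(C_1,\dots,C_k) \;=\; \sum_k \frac{W_{kk}}{A_k + W_{ki}},$$

a per-cluster score in $[0,1]$ that is 1 exactly for an isolated clique and
degrades both when the cluster is internally sparse and when it is strongly
coupled to the rest of the network. Because the denominator adapts to the
cluster's own size and boundary, dense regions may yield dense clusters and
sparse regions sparse ones — no global density target is imposed.

Three classical bipartition objectives are also provided, with
$W_{12}$ the cut between the two sides, $d_i$ the degree mass of side $i$:

* Min–Max cut $\mathrm{JM} = W_{12}/W_{11} + W_{12}/W_{22}$,
* Ratio cut $\mathrm{JR} = W_{12}/|V_1| + W_{12}/|V_2|$,
* Normalized cut $\mathrm{JN} = W_{12}/d_1 + W_{12}/d_2$.

These are defined for bipartitions only. To use them as GA fitness over $k$
clusters the package generalizes them as
$-\sum_k W_{ki}/D_k$ with $D_k$ the internal edge count (minmax), cluster
size (ratio), or degree mass (normalized). This multiway form is the
package's own construction — the two-way definitions do not dictate one —
chosen so that it (i) reduces to the negated two-way objective on a covering
bipartition with non-degenerate sides and (ii) shares the "higher is better"
orientation of JD, so the GA loop is objective-agnostic.

Two deliberate conventions:

* **Zero denominators.** In per-cluster sums (JD and the multiway
  objectives) a term with zero denominator contributes 0, so degenerate
  clusters are unrewarded but never crash a run. In the two-way objectives a
  zero denominator under a non-zero cut returns `Inf` — the worst possible
  split — which is the right signal for the spectral recursion's
  split-acceptance test.
* **Duplicate clusters count once.** Fitness is evaluated on the *distinct*
  clusters of an individual. A per-cluster sum would otherwise reward
  carrying $k$ identical copies of the single densest clique, a degenerate
  optimum that contradicts the goal of covering the network; merging
  duplicates at evaluation matches the post-processing rule that merges them
  in the final prediction.

Even with duplicates merged, the unconstrained optimum of JD over
*overlapping* clusterings can exceed the best exclusive partition: on the
path $a\!-\!b\!-\!c$, the pair $\{a,b\},\{b,c\}$ scores $1/2 + 1/2 = 1$
while the best partition scores $2/3$. The same happens on denser graphs
via near-duplicate clusters that differ by a node or two. This is a real
property of the objective, not a bug: the package's tests therefore treat
the exhaustive-partition optimum as a floor the GA must reach, not a
ceiling it cannot exceed, and readers should expect the GA to return more
clusters than there are "true" modules when the fitness profits from
overlap (see *Limitations*).

## Spectral initialization

The recursive bisection works on the generalized eigenproblem
$Qx = \lambda D x$, with $Q = D - A$ the combinatorial Laplacian of the
current subgraph and $D$ its diagonal degree matrix — the spectral
relaxation of the normalized cut, which is why JN is the default
split-acceptance score. The solver takes the eigenvector of the
second-smallest eigenvalue of the symmetric normalized Laplacian
$D^{-1/2} Q D^{-1/2}$ (dense `eigen()`; the networks this package targets
are small enough that a sparse iterative solver would buy nothing) and maps
it back by $x = D^{-1/2} y$. Nodes are split by one-dimensional 2-means on
the components of $x$, initialized deterministically at the minimum and
maximum component with assignment ties broken toward the lower centroid, so
the whole procedure is reproducible byte for byte. A subgraph is split
while the accepted split's objective value stays below `split_threshold`
(default 1.0 for JN, whose bipartition values lie in $[0,2]$; the midpoint
is the natural "indifferent" level) and both children reach
`min_cluster_size`.

Disconnected subgraphs never reach the eigensolver: connected components
are separated first, which avoids the singular pencil of a disconnected
Laplacian, and degree-zero proteins become singleton clusters immediately.
The sign of the Fiedler vector is fixed (largest-magnitude component made
positive) for determinism. The split evaluated is the one 2-means produces;
no sweep over all threshold cuts of $x$ is attempted, keeping the
initialization cheap and faithful to the bisection description.

## The genetic algorithm

Each generation: evaluate, copy the `elitism` best individuals unchanged,
fill the rest by fitness-proportionate (roulette-wheel) selection followed
by mutation. Crossover is deliberately absent — recombining two clusterings
scrambles good clusters faster than it assembles them — so mutation is the
only variation operator and `mutation_rate` defaults to 1. Selection
probabilities use fitness shifted by the population minimum plus a small
epsilon, so negative fitnesses (the multiway objectives) are handled and an
all-equal population degrades to uniform sampling; tournament selection is
available as an alternative. Elitism makes the best-fitness trace monotone
non-decreasing, which the tests assert across seeded runs.

Mutation picks one (cluster, member) occurrence uniformly and either
**moves** the member to another uniformly chosen cluster (probability
`move_prob`, default 0.5) or **expands** the cluster by the member's whole
network neighborhood. Expansion is the overlap-creating move: neighbors are
added regardless of where else they already sit. Both moves preserve
validity (clusters stay duplicate-free sets over valid indices) and
invalidate only the touched clusters' cached fitness terms, so a generation
costs far less than re-scoring every cluster of every individual.

Random initialization gives each of the $k$ lists $\lceil N/k \rceil$
uniform draws with replacement (repeats collapse; collisions across lists
create overlap); any protein still unassigned is appended to a uniformly
chosen cluster, so the discard ratio of the final prediction reflects
post-processing, never initialization gaps. $k$ defaults to
$\max(2, \lfloor N/10 \rfloor)$, one cluster per ten proteins, the typical
complex scale in curated yeast catalogs. Spectral initialization uses the
spectral clustering itself as individual one and 1–3 mutations of it for
the rest; $k$ is then the spectral cluster count and stays fixed during
evolution (empty lists can be repopulated by moves).

The run stops at the generation budget or after `stagnation` (default 50)
generations without improvement — the only stopping rule that is testable.
Post-processing drops clusters below `min_complex_size` (default 3, the
usual convention for predicted complexes), merges duplicates, and orders
the result canonically.

## Evaluation against reference catalogs

A predicted cluster $C$ is matched to the reference complex $G$ minimizing
the hypergeometric upper-tail p-value of their overlap,

$$p = 1 - \sum_{i=0}^{k-1} \binom{M}{i}\binom{N-M}{n-i}\Big/\binom{N}{n},$$

with $N$ the network size, $M = |G \cap \text{network}|$ (complex members
absent from the network cannot be drawn, so they leave the urn), $n = |C|$
and $k = |C \cap G|$; ties break toward larger overlap, then lexicographic
complex name. The tail is computed through `stats::phyper()`, which works
in log space and is stable far into the tail. Best-match p-values are
Benjamini–Hochberg corrected across clusters by default and gated at
`alpha = 0.05`; neither threshold nor correction is canonical in this
literature, so both are explicit arguments.

Per-match precision, recall and F follow the set definitions
$P = |C \cap G|/|C|$, $R = |C \cap G|/|G|$, $F = 2PR/(P+R)$. The aggregate
row reported by `glance()` is a documented choice: precision averages the
best-match $P$ over significant clusters (cluster-side view), recall
averages over reference complexes with at least one network member the best
$R$ any significant cluster achieves for them, 0 when unmatched
(complex-side view), and the aggregate F is the harmonic mean of the two.
The discard ratio counts proteins in no predicted complex. Other
aggregation conventions exist; comparisons across tools should use one
convention for all of them, which `compare_methods()` does.

## The planted-complex generator

`simulate_planted_network()` emulates exactly the structure the method
assumes: modules denser inside than outside. Complex sizes are uniform in
`size_range`; designated pairs share `shared_count` proteins; every pair of
proteins sharing a complex is joined with probability `p_in` and every
other pair with `p_out` (one uniform draw per pair, so raising `p_out` at a
fixed seed only ever adds edges); filler proteins belong to no complex. The
defaults — six complexes of ten, $p_{in} = 0.8$, $p_{out} = 0.02$ — are the
benchmark condition used throughout the tests: ten proteins is a typical
curated-complex size, 0.8 makes complexes dense but far from cliques, and
0.02 matches the sparsity of high-confidence yeast interactomes.

What the generator does *not* emulate: the power-law degree distribution,
the correlated false positives/negatives of affinity-purification data, and
size heterogeneity of real catalogs. Passing the planted benchmarks
therefore demonstrates that the optimization machinery recovers modular
structure at realistic density contrast — not that any particular biological
catalog will be recovered at the same rates.

## Problem sizes and numerical choices

The test suite and acceptance script run, per replicate, networks of 30–60
proteins with GA populations of 15–80 over up to 200 generations and 20
replicate seeds — sizes at which exhaustive oracles (all set partitions of
8 nodes, all bipartitions of 10 nodes, direct hypergeometric summation at
$N \le 30$) are feasible, so every core quantity is checked against an
independent enumeration rather than against itself. Interactome-scale
statistics are exercised on a 1,004-protein, 8,319-interaction random
graph, the scale of the Collins yeast network, whose average degree
$2E/N = 16.57$ and density $E/\binom{N}{2} = 0.0165$ depend only on those
two counts. Eigensolves validate against a residual contract
$\|Qx - \lambda Dx\| \le 10^{-8}\|Q\|_F$; 2-means on the Fiedler vector is
run to convergence with a 100-iteration cap it never reaches in practice.

## Limitations

* The GA's cluster count is anchored by the initialization ($k$ is fixed);
  with the density fitness and overlap allowed, converged populations often
  hold near-duplicate variants of the same module, so predicted complex
  counts exceed the true module count when the fitness profits from
  overlap. Tighter `split_threshold` (fewer, larger spectral seeds) or a
  larger `min_complex_size` are the practical dials.
* Objectives are computed on unweighted edges by default; confidence
  weights are carried by the network container and used in the cut
  objectives, but the benchmark conditions and tests are unweighted.
* Aggregate precision/recall conventions differ across published
  comparisons; absolute aggregate values are only comparable within one
  convention.
* The dense eigensolver makes recursive bisection $O(n^3)$ per block;
  adequate for curated networks of a few thousand proteins, not for
  organism-scale interactomes beyond that.
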