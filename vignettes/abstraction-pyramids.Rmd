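---
title: "Abstraction pyramids from weighted networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abstraction pyramids from weighted networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyramabs)
```

# The problem

Module-level analyses of biological networks usually commit to one of two
views: a dendrogram that records which modules contain which (vertical,
inclusion relationships) or a single flat network of modules (horizontal,
inter-module relationships). An abstraction pyramid combines the two: every
level is a network of supernodes that coarsens the level below it, vertical
links encode inclusion, and the weighted horizontal links at each level
quantify how strongly the modules of that level associate. `pyramabs` builds
such pyramids from any weighted, optionally directed network given as an
edge list, with no prior domain knowledge.

# The proximity measure

All structure discovery rests on a topology-only association measure between
ordered node pairs. With `A` the weighted adjacency matrix and
`W_i = sum_m A_im` the outgoing strength of node `i`,

$$prox(i,j) = A_{ij} + \sum_{k:\,A_{ik}>0,\,A_{kj}>0}
  \frac{A_{ik}}{W_i - A_{ij}}\cdot\frac{A_{kj}}{W_k}\cdot\min(A_{ik},A_{kj}).$$

The direct link contributes its full weight. Each common neighbour `k`
contributes the probability that `i` influences `k` (excluding the direct
route to `j`) times the probability that `k` influences `j`, scaled by the
weaker of the two link weights. Two remarks that matter in practice:

* The measure is *directed even for undirected input*: the denominator
  `W_i - A_{ij}` belongs to the source node, so `prox(i,j) = prox(j,i)`
  holds exactly only when all node strengths are equal (for example on
  weight-regular graphs). On the triangle `i–j–k` with a pendant neighbour
  on `i` and unit weights, `prox(i,j) = 1.25` while `prox(j,i) = 1.5`.
  Downstream code therefore treats proximity matrices as directed
  throughout, and supernode networks inherit a directed flag whenever their
  matrix is asymmetric.
* A node with no outgoing links contributes no outgoing proximity; the
  denominator `W_i - A_{ij}` is positive whenever the indirect sum is
  non-empty, so no special-casing beyond that is needed.

For unweighted networks (all weights 1) the indirect terms are small
(each path contributes roughly `1/(deg^2)`), so proximity behaves like the
adjacency plus a common-neighbour bonus; the bonus is exactly what lets the
spanning-tree backbone prefer within-module links.

# Search-space reduction by z-score

At each level, all stored proximities (both directions pooled) are
standardized with their population mean and population standard deviation,
and pairs below the z-score threshold are discarded (`z_threshold`,
default 0, i.e. keep the above-average half). Conventions:

* Population, not sample, standard deviation; with a single stored pair the
  deviation is zero and everything is kept — a uniform level should never
  lose all of its links.
* The keep rule is closed (`z >= threshold`) since links strictly *below*
  the threshold are the ones discarded.
* Zero-proximity pairs are never materialized, so they are not part of the
  population being standardized.

Thresholding is a search-space reduction, not part of the model: the
supernode weights of the next level are computed from *un-thresholded*
proximities (see below), and filtering is re-applied only when the next
level's proximity is standardized in its own turn.

# Backbone and partition

The two directions of each surviving pair are summed
(`w(i,j) = prox(i,j) + prox(j,i)`) and a maximum-weight spanning tree is
built per connected component (Kruskal; ties broken by decreasing weight,
then lexicographic endpoint names, so runs are bit-for-bit reproducible).
Isolated nodes become single-node trees.

Modules are sub-forests of this backbone. A module set `M` is *valid* when
for every pair `(M_a, M_b)`,

$$S_{intra}(M_a) > S_{inter}(M_a,M_b)
  \quad\text{and}\quad S_{intra}(M_b) > S_{inter}(M_a,M_b),$$

where `S_intra(M) = sum_{i,j in M} prox(i,j)` runs over ordered pairs
within `M` and `S_inter(M_a,M_b) = sum_{i in M_a, j in M_b} prox(i,j)` runs
over one ordered direction; the quantifier over ordered module pairs means
each intra sum must beat the inter sum *in each direction* (equivalently,
the larger of the two). All sums are evaluated on the full thresholded
proximity network, never on the tree — the tree only proposes candidate
module boundaries. Pairs with zero mutual proximity are exempt, which is
what allows genuinely disconnected modules (including isolated singleton
supernodes, which are kept and flagged).

The partition procedure is sequential validated link removal:

1. Start with one module per backbone tree.
2. Examine tree links from weakest to strongest (ties lexicographic).
3. Tentatively remove a link; this splits its module into the two
   sub-trees on either side. Commit the removal only if the *global*
   module set remains valid — both new modules must beat their mutual
   inter sums and their inter sums against every existing module. (The
   existing modules' own conditions cannot break: splitting a neighbour
   only lowers the inter sums they face.)
4. Refused links are restored. Passes over the remaining links repeat
   until a full pass commits nothing.

Because every committed state is valid, the final module set satisfies the
criterion pairwise by induction; a final validation pass re-checks all
pairs and would merge any violating pair (smallest violation first), but is
a safety net that normal runs leave untouched. The weakest-first order
matters: on a maximum spanning tree the weakest links sit between the
coarsest natural groups, so removal proceeds coarse-to-fine, and a split
that would isolate a fragment too weak to stand as a module is simply
refused and revisited after the surrounding structure has been carved out.
Alternatives we evaluated and rejected: choosing among admissible cuts by
minimum inter sum first peels small dense fragments before the meaningful
coarse cuts, and recursive designs that *merge* violating pairs afterwards
can cascade — a large module that violates against a small neighbour
swallows it, growing until whole branches collapse. Refusal-based
validation has neither failure mode.

# Abstraction and iteration

Each module becomes a supernode, and the proximity between two supernodes
is the size-normalized sum of member proximities,

$$prox_{super}(M_a, M_b) = \frac{1}{|M_a||M_b|}
  \sum_{m \in M_a,\, n \in M_b} prox(m,n),$$

computed from the *un-thresholded* proximities of the current level so
that module pairs connected only through below-threshold links are not
silently zeroed. The supernode network is the next level's input; the
whole cycle (proximity, z-filter, backbone, partition, abstraction)
repeats until the abstract network has a single node. A level is one
partition/abstraction stage, numbered from the top as in printed
hierarchies: a five-level decomposition with module counts 207/72/16/3/1
has the single-root stage as level 1.

Two safeguards that the iteration needs in practice:

* **Stall detection.** If a level refuses to coarsen at all (as many
  modules as nodes) or the `max_levels` bound (default 50) is reached, the
  pyramid is returned with `stalled = TRUE` instead of looping forever; a
  link-free level likewise stalls with every node its own flagged module.
* **Trivial input.** A single-node network yields one trivial level and is
  a success, not a stall.

# The nested random-network generator

Validation uses hierarchically nested random networks with a planted
three-level structure: 640 nodes in 4 top-level modules of 160, each split
into 4 modules of 40, each split into 4 bottom modules of 10. Edge
probability depends only on the hierarchical distance `d` between two
nodes (`d = 0`: same bottom module; `d = 3`: no shared module) through a
geometric tier law

$$p_d = c\,\rho^d, \qquad 0 < \rho < 1,$$

with `c` calibrated in closed form so the expected edge density equals the
target (default 0.0225): with partner counts `m_d` per node
(9, 30, 120, 480 at the defaults), `c = density * (n-1) / sum_d m_d rho^d`.
At the default `rho = 0.25` this gives `p_0 ~ 0.456`. Calibrations that
would need `p_0 > 1` are refused with advice to raise `rho` or lower the
density. Sampling is one independent Bernoulli draw per unordered pair;
the planted partition is returned alongside the network, and everything is
reproducible from one seed. Density sweeps use exact-count thinning
(uniformly random link removal to the exact target link count) so the
swept variable is noiseless.

What the generator emulates is the *community structure* of the original
benchmark ensemble: planted nested blocks with geometrically decaying
cross-scale connectivity. What it does not emulate: degree heterogeneity
(all nodes share one expected degree), weights (unit), directedness, or
any feature of real interactomes such as hubs and spoke patterns — so
passing recovery tests here demonstrates correctness of the machinery on
block-structured data, not performance on real biological networks.

# Cohesion and the limits of the partition criterion

The single knob `rho` controls how cohesive the planted levels are, and
the partition criterion has a sharp working range in it. Two expectations
under the tier law make the trade-off explicit (unit weights, defaults,
bottom modules of 10):

* *Fragmentation resistance.* Splitting a bottom module into parts of 4
  and 6 pits an intra sum of `~12 p_0` against a one-way inter sum of
  `~24 p_0`: invalid *in expectation* at any `rho`. But at `p_0 ~ 0.46`
  the blocks are sparse Bernoulli graphs with large relative fluctuations,
  and samples containing a dense 3–6 node subset with a sparse boundary
  satisfy the criterion; the weakest-first descent then legitimately
  carves them out, fragmenting the bottom level. As `p_0 -> 1`
  (near-clique bottom modules, `rho ~ 0.12` at the default density) the
  fluctuations vanish and fragment splits essentially never validate.
* *Separability.* Splitting one bottom module off its three siblings pits
  `~90 p_0` (intra) against `~300 p_1 = 300 p_0 rho` (one-way inter), so
  the planted boundary is admissible in expectation whenever `rho < 0.3`,
  with margin growing as `rho` falls.

Hence recovery of the planted hierarchy is reliable in the cohesive regime
and degrades as `rho` grows toward sparse, fluctuation-dominated bottom
modules — the same qualitative dependence the density and threshold sweeps
trace (`run_density_sweep()`, `run_threshold_sweep()`). The package keeps
`rho = 0.25` as the generator default to represent a moderately cohesive
ensemble; users validating the partition machinery itself should do so in
the cohesive range, e.g.:

```{r cohesive-example, eval = FALSE}
gen <- generate_nested_network(rho = 0.125, seed = 1)
pyr <- build_pyramid(gen$network)
module_counts(pyr)                       # 1, 4, 16, 64 at full cohesion
evaluate_hierarchy(pyr, gen$truth)
```

# Evaluation

Recovered hierarchies are scored against planted truth with normalized
mutual information, `NMI = 2 I(P;Q) / (H(P) + H(Q))` with natural-log
entropies over the joint contingency table. The normalization is chosen
for its `[0, 1]` range so "perfect recovery" is exactly 1; conventions for
degenerate partitions: two all-in-one partitions score 1 (they are
identical), one all-in-one against anything informative scores 0.

Levels are aligned *bottom-anchored*: both hierarchies are anchored at the
original nodes, so the finest recovered level scores against the finest
planted level and so on upward, after discarding single-module apex levels
(which carry no partition information). A pyramid may legitimately grow an
extra coarse level above the planted root scale — the analogue of a
3-module level above a 16-module level in a real hierarchy — and
top-anchored matching would misscore an otherwise exact recovery; extra
coarse levels are therefore ignored, while a pyramid with *fewer*
informative levels than the truth scores the unmatched truth levels
against its closest level and flags them.

# Enrichment statistics

For annotated networks the package quantifies module coherence without any
external service, against a user-supplied node-to-category table:

* `hypergeometric_pvalue(k, n, K, N)`: upper-tail probability of observing
  `k` or more category members in an `n`-node module, via the survival
  function (numerically stable in the far tail).
* `module_enrichment()`: per-category p-values over the annotated
  background; the minimum raw p is reported by default (Bonferroni across
  tested categories behind a flag), matching the common raw-p reporting
  convention for module tables. The analytic hypergeometric tail is the
  exact closed form of the random-assignment null.
* `p_decrease_ratio(pv_a, pv_b, pv_ab) = (min(pv_a,pv_b) - pv_ab) /
  min(pv_a,pv_b)`: positive exactly when merging two modules is more
  significant than either alone.
* `proximity_signtest()`: across all pairs of abstract-network links with
  strictly different proximities, tests whether the stronger link's merge
  yields the larger p-value decrease, with a one-sided exact binomial sign
  test against chance 1/2 (ties in the decrease ratio are excluded, the
  standard sign-test convention; ties in proximity are not comparable and
  are skipped).

# Numerical and design conventions in one place

* Strict inequalities in the partition criterion; zero-inter pairs exempt.
* Population SD in the z-filter; `sigma = 0` keeps everything.
* Deterministic orders everywhere (Kruskal: weight desc then lexicographic;
  link removal: weight asc then lexicographic; module ids by first member
  in node order), so identical inputs give identical pyramids.
* Duplicate edge-list records merge by summation (total evidence), with a
  warning; self-links are dropped with a warning; unweighted records
  default to weight 1.
* Supernode matrices are exactly symmetrized (and flagged undirected) only
  when numerically symmetric; otherwise they stay directed.
* All randomness flows through explicit seeds (`generate_nested_network`,
  `thin_to_density`, sweep harnesses derive per-task seeds from one master
  seed and record them in the report's `config` attribute).

# Problem sizes used in the test suite

The bundled tests validate the exact oracles on graphs of up to 7 nodes
(spanning forests, against exhaustive search over all trees), up to 6
nodes (proximity, against brute-force path enumeration), and exercise the
full pipeline on 640-node benchmark networks and 20–45-node nested
fixtures; the enrichment tails are checked against direct combinatorial
enumeration up to `N = 12`. These sizes keep the default test run fast
while covering every code path; the package itself comfortably handles the
2,440-protein scale of a typical core interactome on a laptop.

# Known limitations

* The partition criterion compares *sums* of proximities, so its decisions
  are scale-aware but fluctuation-sensitive on sparse modules (see the
  cohesion section); it has no resolution parameter.
* Modules never overlap; a node belongs to exactly one module per level.
* The proximity measure looks two steps out. Modules bound together only
  by longer-range structure are invisible to it until abstraction shortens
  the paths.
* On networks with no modular structure at all the method returns few,
  large modules or stalls — the stall flag, not an error, reports this.
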