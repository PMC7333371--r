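---
title: "Methods behind senonet: seed-gene networks, permutation nulls and screen scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind senonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senonet)
```

`senonet` packages the statistical machinery used to analyse a curated
catalog of cellular-senescence regulators: network construction anchored
on the catalog's genes, topological discovery of new candidate
regulators, directional overlap enrichment against differential-expression
panels, a permutation null for multi-tissue expression counts,
conservation statistics on phylogenies, and Z-score hit calling for an
siRNA validation screen. This vignette records the models, the parameter
choices, and the numerical conventions, in enough detail that every
result the package produces can be re-derived by hand or against an
independent oracle.

## Density-minimising correlation thresholds

A co-expression network at threshold $t$ keeps the gene pairs with
Pearson correlation $r \ge t$ (signed by default; an `absolute = TRUE`
mode thresholds $|r|$, but co-expression databases rank positive
co-expression, so signed is the default). Its density is

$$D(t) = \frac{E(t)}{\binom{N(t)}{2}},$$

where $E(t)$ is the number of kept edges and $N(t)$ counts only the genes
incident to at least one kept edge. Counting incident nodes — rather than
all genes in the matrix — is the only reading under which raising the
threshold trades *more nodes against fewer edges* and produces an
interior density minimum; with a fixed node universe, density would be
monotone in $t$. Thresholds that keep zero edges have undefined density
and can never be selected. Ties are broken toward the lowest threshold,
which keeps the most catalog genes in the network and therefore the most
representative network. The default grid is 0.00–0.99 in steps of 0.01,
matching the resolution at which such thresholds are conventionally
reported.

The seed-anchored network at the selected threshold starts from the seeds
present in the matrix and their super-threshold partners, then keeps
every super-threshold edge with at least one endpoint in that set; the
network's nodes are the endpoints of the kept edges. Partner–partner
edges are therefore retained, a gene beyond the partners can enter
through such an edge, and no further expansion happens from those genes.
This mirrors the first-order rule used for physical interaction networks:
seeds, their direct interactors, and *all* input edges within that node
set (interactor–interactor edges included), after removing self-loops and
duplicate edges. Gene identifiers are compared case-sensitively after
whitespace trimming; alias and orthologue mapping is out of scope.

## Topology and candidate discovery

All centralities are computed within connected components, since
seed-anchored networks typically carry tiny satellite components:

- **Degree** — incident edge count.
- **Betweenness (BC)** — shortest-path betweenness divided by
  $\binom{n-1}{2}$ pairs of the node's component, so it lies in $[0,1]$.
- **Closeness (CC)** — the reciprocal of the *mean* shortest-path
  distance to the reachable nodes. Defined this way, higher CC means
  more central, consistent with the inverse-distance formula; "top CC"
  throughout the package means largest. Isolated nodes get 0.
- **Local clustering** — realised neighbour–neighbour edges over possible
  ones, 0 for degree < 2.
- **Increased connectivity (IC)** — for node $v$ with $k$ neighbours of
  which $x$ are seeds, the hypergeometric upper tail
  $P(X \ge x)$ when drawing $k$ from the other $N-1$ nodes of $v$'s
  component, $K$ of them seeds ($v$ excluded from the seed count when it
  is itself a seed). The component is the sampling universe because a
  node cannot draw neighbours outside its component. p-values are
  BH-adjusted across all nodes, and significance is called at adjusted
  p < 0.05; whether a raw or adjusted cutoff is used is configurable, the
  adjusted one being the default.

The scale-free character of a network is summarised by least squares on
$(\log k, \log f(k))$ over degrees with nonzero frequency — the network
topology tool convention, chosen for comparability with correlation/R²
style reporting — rather than maximum-likelihood tail fitting. At least
three distinct degrees are required for a fit.

**Candidate ranking.** A node qualifies when it is in the top 1% tier of
at least two of degree, BC and CC, or when it has significant IC and is
in the top 5% tier of at least one of them (both tiers configurable).
"Top $p$%" is membership in the $\lceil p/100 \cdot n \rceil$ best ranks,
ties sharing the better rank. Seeds are flagged but kept, since known
regulators scoring highly are informative; `novel_only = TRUE` restricts
the output to genes not already in the catalog. Ordering is by the
number of qualifying criteria, then BC descending, then label — so the
output is invariant to node relabelling up to tie order.

**Module detection.** The edge-clustering-value agglomeration is fully
specified here because the clustering tool it emulates documents only its
parameters, not its internals; reproducible behaviour was preferred over
tool mimicry. For each edge,
$\mathrm{ECV}(u,v) = |N(u) \cap N(v)|^2 / (|N(u)\setminus v| \cdot
|N(v)\setminus u|)$, zero when a factor vanishes. Edges are processed in
decreasing ECV (ties lexicographic). An edge attaches an unassigned
endpoint to the other endpoint's cluster; an edge between two clusters
merges them only when the merged cluster is weak in the Radicchi sense at
scale $\lambda$ (internal degree $\times \lambda/2$ > external degree; at
the default $\lambda = 2$ this is the plain internal > external rule).
Zero-ECV edges never merge two formed clusters: a single bridge between
two communities carries no shared-neighbourhood evidence, and processing
it would fuse any two communities (the whole-graph weak test is trivially
satisfied). Clusters below `min_size_fraction` (default 1%) of the node
count are discarded.

## Overlap statistics

Overlap of two gene sets in a universe is tested with the exact
hypergeometric distribution; one-sided "greater" is the default for
enrichment claims, "less" for depletion, and the two-sided p sums all
tables at most as probable as the observed one (the `fisher.test`
convention, against which the implementation is cross-checked). The
reported odds ratio is the sample odds ratio
$k(N-a-b+k) / ((a-k)(b-k))$ with $\infty$ when a denominator cell is 0
and 0 for an empty input set. The BH family is one analysis table — e.g.
all cells of a heat matrix — matching per-figure correction practice.

Genes differentially expressed in *both* directions across a tissue panel
are counted once in each directional list, and the universe is inflated
by one per such gene, keeping the contingency tables consistent. Heat
values are signed: $-\log_2 p_{\mathrm{enriched}}$ when the observed
overlap exceeds expectation $ab/N$, $+\log_2 p_{\mathrm{depleted}}$ when
below, 0 exactly at expectation. Distribution shifts in fold change are
tested with the two-sided Wilcoxon rank-sum test, exact up to a combined
sample size of 20 (testable by full enumeration: 5-vs-5 disjoint samples
give exactly $2/252$) and a continuity-corrected normal approximation
above. The universe for every overlap is caller-supplied — the genes
actually measured — never a hardcoded genome size, because published
overlap p-values generally depend on unstated backgrounds.

## The tissue-scrambling permutation null

The question: how many tissues would a catalog gene be significantly
differentially expressed in *by chance*? Within each tissue, the multiset
of (adjusted p, fold change) pairs is permuted uniformly across that
tissue's genes — pairs are never split, tissues are independent — and the
significance filter (adjusted p < 0.05, |effect| > log₂1.5) is re-applied.
Input p-values are treated as already adjusted: the procedure scrambles
published per-tissue results rather than recomputing tests. Effects are
stored on the 50-year scale; per-year inputs can be rescaled on read
(`per_year_scale = 50`), keeping one unambiguous internal unit.

Across `n_sim` rounds (default 10,000, seed mandatory) the per-direction
tail $P(\text{count} > k)$ is the fraction of simulation × gene
observations exceeding $k$ — pooled across the catalog genes' tissue
presence patterns, since a gene absent from a tissue's table can never be
significant there and contributes probability zero for that tissue. (An
alternative estimator — the per-simulation maximum over genes — would
answer a family-wise question; the pooled per-gene estimator matches the
per-gene flagging rule and is the one implemented.) The cutoff
$k^\*$ is the smallest $k$ with tail below 5%, and a gene is flagged when
its observed count *strictly* exceeds $k^\*$ ("more than $k^\*$
tissues").

Because scrambling preserves each tissue's significant-set sizes exactly,
a gene present in tissue $t$ is significant-up there with probability
$m_t/G_t$, independently across tissues; the count is therefore
Poisson-binomial, and `poisson_binomial_tail()` computes the exact tail
by dynamic programming. This closed form is the oracle the simulation is
tested against (agreement within 3 Monte-Carlo standard errors at
`n_sim = 2000` on a 10-tissue panel).

## Conservation statistics

Orthologue enrichment per species is a pooled two-proportion z-test with
a two-tailed normal p, BH-corrected across species. Faith's PD of a tip
subset is the branch-length sum of the minimal spanning subtree, plus the
MRCA-to-root path under `include_root = TRUE` — the default, because the
established R implementation includes the root path and the choice
changes single-tip PD materially (a single tip has PD equal to its
root-path length with the root, 0 without). Under independent binomial
tip sampling at probability $p$, branch $b$ with $n_b$ descendant tips is
covered with probability $1-(1-p)^{n_b}$, giving the closed-form
expectation; no conditioning on at least one sampled tip is applied,
matching the plain binomial expectation. Polytomies are accepted as-is
and zero-length branches contribute 0. The sampling probability is an
explicit parameter rather than being matched to an observed tip count.
The implementation is cross-checked against `picante::pd` in the test
suite.

## Screen scoring

Z-scores are computed per experiment against the negative-control
(cyclophilin B) wells, `(target mean − control mean) / control SD`, and
averaged *unweighted* across experiments (replicate-count weighting is
not reported in screening practice we emulate; unweighted is the
documented choice). Each experiment needs ≥ 3 control wells with nonzero
SD; violations abort with the experiment and marker named. Positive
controls are carried through but never enter the Z computation.

Marker flags fire at 1 Z in the senescence-associated direction: Ki67 and
cell number down; cell area, nuclear area, p16, p21, IL-6 and SA-β-gal
up. Ki67 uses a strict inequality (a decrease *greater than* 1 Z); the
remaining markers flag at the boundary (≥), and the direction map is
configurable. "Altered at least one morphological measure" means a
senescence-direction increase of cell or nuclear area (an
either-direction relaxation at $|Z| \ge 1$ is available). A top hit
requires the Ki67 flag, the cell-number flag and a morphology flag.
Summary percentages are rounded half-up to one decimal — plain `round()`
banker's rounding misreports boundary fractions.

## What the synthetic generators emulate — and what they do not

- `gen_expression` plants correlated modules through a shared latent
  factor: gene $= \sqrt{r}\,f + \sqrt{1-r}\,\varepsilon$, which gives an
  expected pairwise within-module correlation of exactly $r$. It emulates
  module structure, not RNA-seq marginals: values are Gaussian, there is
  no mean–variance relation, no library-size effect, and no negative
  correlation structure. Passing tests show the thresholding and module
  machinery recovers planted correlation structure, not that it is robust
  to count noise.
- `gen_scalefree_graph` uses preferential attachment from an
  `m_attach`-clique, which pins the edge count at
  $\binom{m}{2} + m(n-m)$ — a deliberately testable construction. The
  optionally planted high-IC node is wired to 75% of the seeds and is
  itself a non-seed, because candidate discovery must be able to find
  genes not already in the catalog.
- `gen_deg_tables` writes already-adjusted p-values with exact per-tissue
  significant counts, so scrambling-based expectations are analytic
  ($m_t/G_t$). Planted genes occupy significant slots in stated tissues.
- `gen_screen` draws control and target wells from per-marker Gaussians
  and shifts designed hits by a fixed number of control SDs (default 3,
  a clearly recoverable effect at the default well counts); plate
  position effects and per-cell segmentation noise are not modelled.
- `gen_tree` grows a Yule topology by splitting a uniformly chosen extant
  tip and assigns exponential(1) branch lengths — adequate for exercising
  PD arithmetic, not a calibrated timetree.

All generators take a mandatory integer seed, restore the caller's RNG
state, and are byte-reproducible given the seed.

## Numerical choices and degenerate inputs

- Genes with zero sample variance are excluded from correlation matrices
  and reported in an attribute; correlating fewer than 3 samples is an
  error.
- Thresholds keeping zero edges → density undefined (NA), excluded from
  selection; an all-NA scan is a selection error.
- The IC p of a node with zero seed neighbours is 1 ($P(X \ge 0)$); the
  empty seed set is a parameter error.
- `detect_modules` tie-breaks edge processing lexicographically, making
  the partition deterministic.
- Percentile tiers use `ceiling(p/100 * n)` ranks with ties sharing the
  better rank, so "top 1%" of 100 nodes is exactly the best rank and ties
  all enter.
- Wilcoxon with full ties cannot be computed exactly; the approximation
  path is taken silently (p = 1 for identical samples either way).
- `poisson_binomial_tail` beyond the support returns 0.
- Scrambling a single-gene tissue is the identity.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data
at sizes chosen to make Monte-Carlo tolerances meaningful while keeping
each check in seconds: 20 generator seeds for recovery rates (planted
high-IC node, screen sensitivity), correlation panels of 12 genes × 400
samples, scale-free graphs of 150–500 nodes, a 10-tissue × 100-gene DEG
panel with 2000 scrambling rounds against the Poisson-binomial oracle,
10,000 draws for the Fisher calibration sweep and 5,000–10,000 tip-sample
draws for expected-PD agreement. Exhaustive-enumeration oracles (overlap
p-values, IC p-values) run on universes ≤ 20 and graphs ≤ 8 nodes, where
enumeration is exact and fast.

## Known limitations

- Printed network statistics of the original studies (node/edge counts,
  centrality means, the 0.65/0.53 thresholds) depend on specific external
  database versions and are not reproduced here; the package implements
  the rules, not those numbers.
- The ECV agglomeration is a fully specified stand-in for the named
  clustering tool; partitions will not match that tool edge-for-edge.
- Directed regulation, weighted edges and orthology mapping are out of
  scope.
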