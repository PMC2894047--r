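---
title: "Network and pathway characterization of disease gene sets with dgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network and pathway characterization of disease gene sets with dgnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgnet)
```

# Scope and model

`dgnet` treats the interactome as a simple undirected graph: nodes are
gene/protein identifiers (upper-cased at ingest, no alias resolution —
identifier mapping is an upstream concern), edges are physical interactions
with provenance and scores deliberately ignored.  Distances are hop counts;
the self-distance is 0.  Pairs of nodes in different components are
*excluded* from distance averages rather than treated as infinite, and every
statistic reports how many pairs were excluded, so a fragmented input cannot
silently shift an average.

The package answers four questions about a disease gene set *S* mapped into
an interactome *G*:

1. **Is *S* wired differently from random genes?**  Degree, characteristic
   shortest-path distance (mean hops from a gene to all other reachable
   nodes), global centrality (mean hops to the other members of *S*, paths
   free to traverse non-members), and the hub fraction, each with a
   resampling p-value.
2. **Does *S* span a coherent subnetwork?**  An approximate Steiner minimal
   tree over *S*, densified to the induced subgraph, compared against
   Erdős–Rényi nulls matched on node and edge counts.
3. **Where does *S* sit relative to the network's tightly bound
   communities?**  k-clique percolation for k = 3…7 and the fraction of *S*
   inside communities.
4. **Which pathways does *S* enrich, how do they crosstalk, and which
   interactome neighbors of *S* carry independent GWAS signal?**

# Empirical significance

All network-level significance in the package is empirical, mirroring how
such quantities are actually distributed in a fixed, idiosyncratic graph.
For a set of size *n* we draw `n_reps` (default 1,000) uniform *n*-node
samples *without replacement from all network nodes* — deliberately not
from any annotation-matched background, so the question asked is "is this
set unusual among all proteins?" — and count samples whose statistic is *strictly* more
extreme than observed in the stated direction.  Strictness means ties do not
count as exceeding, which makes the boundary values attainable and
interpretable: p = 0 ("no random set outperformed the observed one") and
p = 1 ("every random set did").  The degenerate corner is documented rather
than hidden: in the G(n, m) null-model test the average degree is constant
across matched draws, so its test always returns p = 0 and is reported for
completeness only.

Resampling calibration is part of the test suite: on the default synthetic
interactome, a uniformly drawn "disease set" yields p-values with mean in
[0.40, 0.60] and no detectable departure from uniformity, while a
degree²-biased planted set is flagged at p ≤ 0.01.

For between-set contrasts the Wilcoxon rank-sum test is exact by full
enumeration over rank assignments whenever the combined sample size is at
most 20 (the enumeration handles ties through midranks, which the standard
exact implementation declines to do), and falls back to the tie-corrected
normal approximation above that; the method used is recorded in the result.

# The Steiner subnetwork

The minimum Steiner tree is NP-hard, so the package uses the classic
metric-closure heuristic: compute pairwise hop distances among mapped
terminals, take the minimum spanning tree of that closure, expand each
closure edge into an actual shortest path, union the paths, and iteratively
prune non-terminal leaves.  On each component this is a 2-approximation,
and the test suite verifies the bound against a brute-force oracle on
hundreds of small random graphs.

Determinism mattered more to us than approximation tightness, so every
tie-break is lexicographic: MST ties break on the sorted terminal-pair
label, and each closure edge expands to the lexicographically smallest
shortest node sequence (walking from the alphabetically smaller endpoint,
always stepping to the smallest-named neighbor that stays on a shortest
path).  Results are therefore bit-reproducible across runs and platforms.

Two conventions are worth knowing:

* **Edge induction is ON by default.**  The tree itself is sparse, but the
  biological object of interest is the induced subgraph on the tree's node
  set, which retains all interactome edges among selected nodes and is
  typically far edge-richer than a tree.  `include_induced_edges = FALSE`
  returns the bare tree (that is also what the approximation guarantee and
  the oracle tests are about).
* **Components with a single terminal contribute that terminal to
  `terminals_unreachable`** rather than producing a trivial singleton
  subnetwork; mapped terminals always partition exactly into included and
  unreachable.

The non-randomness test simulates `n_reps` G(n, m) graphs with the observed
node and edge counts and
reports, per metric, the null mean, the null SD and the strict-exceedance
empirical p — direction "greater" for clustering, both tail counts for the
shortest-path distance (reported two-sided as twice the smaller tail,
capped at 1).  Degree-preserving (switching) nulls are deliberately out of
scope.

# k-clique communities

Cliques are of fixed size k (larger cliques contribute all their
k-subsets), and two k-cliques are adjacent when they share exactly k − 1
nodes; communities are node unions of the components of this relation, and
an isolated k-clique is a community of its own k nodes.  Since two distinct
k-cliques share k − 1 nodes precisely when they share a (k − 1)-subset,
adjacency is resolved by hashing each clique's k leave-one-out subsets —
linear in the number of cliques rather than quadratic.  The implementation
is checked for exact equality against a naive enumerate-everything oracle
on a hundred random graphs.

Clique enumeration is exponential in the worst case, so the function
refuses, with guidance, beyond a configurable clique-count budget (default
10⁶).  When a gene set's "fraction in communities" is computed, the
denominator is the set's overlap with the *network the communities were
detected on*; the union of community members is used in the numerator (tools differ in
how they count nodes of overlapping communities, so we fixed the most
transparent convention).  A useful structural
fact: any node in a (k+1)-clique is also in a k-clique, so the membership
fraction is automatically non-increasing in k.

# Pathway enrichment and crosstalk

Enrichment is a one-sided Fisher exact test per pathway against a
background defaulting to the union of the interactome's genes and the
pathway collection's genes (commercial pathway suites score against their
own internal backgrounds, which are not reproducible outside them).  The
pass filter is score = −log₁₀(p) > 2 *and* more than 5 disease genes in
the pathway, i.e. enriched means p < 0.01 with a non-trivial overlap.

Crosstalk between two enriched pathways compares the pair's shared gene
count n (and, separately, shared induced interactome edges — a "link" is a
PPI edge between two genes both inside a pathway, whether or not a pathway
database would annotate that edge) against the across-pairs averages:
the 2×2 table is (n, N − n, r, R − r) with N the *sum* of the two pathway
sizes (shared genes counted twice; a union-based N is available behind the
`n_total` flag), r the mean of n over all unordered pairs (self-pairs
excluded) and R the mean of N.  The averages are rounded half-up for the
exact test, which needs integer counts; the unrounded values stay in the
output.  Node and link p-vectors are BH-adjusted separately; a pair has
crosstalk when min(p_nodes, p_links) < 0.01 (applied to the raw smaller
p-value; the adjusted q-values are reported alongside).  At least 3 pathways are
required, otherwise the across-pairs averages are not meaningful.

`fisher_exact_2x2` computes the hypergeometric tail directly (two-sided =
all tables at the observed margins with probability ≤ the observed table's,
the same rule `stats::fisher.test` uses) and is swept against a full
enumeration oracle on every table with margins ≤ 12 in the test suite.

# GWAS prioritization

Gene-level p-value tables (smallest marker p per gene, produced upstream)
from two independent studies are combined by intersection: a gene is joint
significant when p < α (default 0.05) in *both* studies; genes missing from
either study are dropped from the universe before anything else.  The
randomization test draws `n_sets` (default 1,000) uniform subsets of the
common-gene universe at the subnetwork's size and reports the fraction with
at least the observed joint count ("not less than" implemented as ≥),
repeated `n_repeats` (default 10) times with seeds derived from the master
seed.  Novel candidates are joint-significant subnetwork genes outside the
seed list; each gets an ego subnetwork of its subnetwork neighbors that are
seeds or joint significant.  The pathway-guided route runs the Steiner
extraction on a pathway's genes and ranks non-seed nodes by their degree in
the extracted subnetwork — the "central connector" heuristic.

The known gene-length bias of smallest-p-per-gene statistics is *not*
corrected; results carry
a caveat field, and the synthetic generator can plant signal on arbitrary
sets so users can measure the bias's impact themselves.

# The synthetic fixture: what it does and does not emulate

`synthetic_config()` defines the default study conditions end to end;
`generate_fixture()` is a pure function of it (every stage draws from its
own stream derived from `master_seed` by a fixed affine scheme, so adding a
stage never perturbs earlier draws).

* **Interactome**: 10,000 nodes grown by preferential attachment
  (3 edges per new node) with triangle closure probability 0.15.
  Preferential attachment with closure was chosen over configuration-model
  alternatives because the pipeline needs *tunable clustering* (for the
  community and null-model tests) with guaranteed connectivity.  The result
  has the heavy-tailed degree distribution the analysis assumes; it does
  not attempt to match the human interactome's exact degree sequence, its
  study bias, or its false-positive structure.
* **Gene sets**: five sets with graded degree-bias exponents
  (2, 1.2, 0.7, 0.35, 0) and sizes (300, 400, 160, 250, 300) emulating the
  cancer / essential / disease / neurodevelopment / neutral contrast, with
  the disease-like set sized like a typical curated candidate list.
  Sampling
  weight ∝ degree^exponent; the cancer-like set additionally concentrates
  in 2-hop neighborhoods ("clique planting") to reproduce the
  clustered-hub phenotype.
* **Pathways**: 12 neighborhood-ball gene sets of 30–50 genes; four are
  seeded with 40% disease genes (disjoint portions of the disease set, so
  overlap among them is only where planted) and two pairs carry a planted
  Jaccard overlap of 0.4.  Ball growth guarantees internal links but makes
  pathways more locally coherent than curated pathway content.
* **GWAS**: two studies over all interactome genes, Uniform(0,1) under the
  null, Beta(0.1, 1) on the disease subnetwork's genes — so
  P(p < 0.05) = 0.05^0.1 ≈ 0.74 per signal gene per study.

Passing tests on this fixture demonstrate that the machinery recovers
planted structure under realistic graph topology; they do not certify
performance on real interactomes, whose ascertainment bias, annotation
error and pathway redundancy the generator intentionally does not model.

# Numerical and interface choices

* **Hub cutoff.**  "Where the degree distribution straightens out" is a
  visual notion, not an algorithmic one.  We operationalize it as
  the smallest integer degree whose upper-tail node share first drops to a
  configurable `tail_fraction` (default 0.21, matching the reported ~21%
  hub share), scanning integer degrees so the cutoff can fall in a gap of
  the observed degrees.  Hubs are nodes with degree ≥ cutoff (non-strict,
  so the cutoff degree itself is a hub).  A manual cutoff is always
  accepted and is the recommended mode for replication work.  A regular
  graph (fewer than three distinct degrees) is an error, not a guess.
* **Ties and determinism.**  All stochastic functions take explicit seeds;
  repeats derive per-repeat seeds.  All ordering tie-breaks (MST edges,
  shortest paths, community sorting, candidate ranking) are lexicographic.
  Writers sort nodes and edges, and the pipeline embeds no timestamps, so
  identical configurations give byte-identical output trees.
* **Degenerate inputs** error early and specifically: empty graphs, absent
  nodes, malformed lines (named by line number), empty pathways,
  out-of-range p-values, set sizes exceeding the universe.
* **Problem sizes in the shipped tests** were chosen to keep the whole
  suite at desk scale: Steiner oracle comparisons on graphs of ≤ 12 nodes
  with ≤ 6 terminals, clique-percolation oracle checks on G(30, 90),
  exact-test sweeps over all margins ≤ 12, calibration on the default
  10,000-node fixture with 200 × 200 resampling draws, and GWAS
  randomization at 1,000 subsets × 10 repeats.

# Known limitations

* Undirected, unweighted graphs only; no edge confidence weighting, no
  directed or signed interactions.
* The Steiner heuristic can return up to twice the optimal tree; exact
  node/edge counts of any specific published subnetwork are not
  reproducible without the original interactome, so they are conventions,
  not validation targets.
* Clique percolation is exponential on dense graphs; the budget guard
  refuses rather than degrades.
* No SNP-to-gene mapping, LD modeling or gene-length correction; gene-level
  p tables are consumed as given.
* No identifier alias resolution; inputs must share a naming scheme.

# Session info

```{r}
sessionInfo()
```
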