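# dgnet — disease-gene network topology, subnetwork extraction, and pathway crosstalk

`dgnet` characterizes a set of disease candidate genes in the context of a
protein–protein interaction (PPI) network.  It is aimed at researchers in
psychiatric and complex-disease genetics who have (i) a prioritized disease
gene list, (ii) an interactome, (iii) a pathway collection, and (iv)
gene-level association p-values from independent GWAS, and who want to know:
how are these genes wired into the interactome, do they form a coherent
subnetwork, which pathways do they light up and how do those pathways talk to
each other, and which interactome neighbors of the disease genes deserve a
closer look?

All of the statistical machinery runs equally on user-supplied files
(edge lists / SIF / GraphML, one-gene-per-line lists, GMT, two-column
gene/p TSVs) and on a built-in synthetic-data generator, so the entire
pipeline is testable offline.

## Methods at a glance

* **Topology with resampling significance.** For a gene set of size *n*
  mapped into the interactome, the package reports per-gene degree *k*, the
  characteristic shortest-path distance (mean hops from a gene to every other
  reachable node), the global centrality (mean hops to the other set members,
  paths free to pass through non-members), and hub fractions at a
  degree-distribution cutoff.  Significance is empirical: draw 1,000 uniform
  random *n*-gene sets, count the draws *N<sub>i</sub>* whose statistic is
  strictly more extreme than observed, and report *p = N<sub>i</sub>/1000* —
  so *p = 0* means no random set outperformed the observed one.  Between-set
  contrasts use the Wilcoxon rank-sum test (exact by enumeration up to a
  combined n of 20).
* **Steiner subnetwork.** The disease-specific subnetwork is the classic
  metric-closure/MST approximation of the Steiner minimal tree over the
  mapped disease genes (2-approximation per component, all tie-breaks
  lexicographic), optionally densified to the induced subgraph on the tree's
  node set.  Non-randomness is tested against 1,000 Erdős–Rényi *G(n, m)*
  graphs matched on node and edge counts (average degree, average
  shortest-path distance, mean clustering coefficient).
* **k-clique communities.** Clique percolation: two *k*-cliques are adjacent
  when they share exactly *k − 1* nodes; communities are node unions of the
  connected components of that relation, for *k* = 3…7, with the fraction of
  a gene set inside communities tracking how "core" vs peripheral it is.
* **Pathway enrichment and crosstalk.** Enrichment is a one-sided Fisher
  exact test per pathway; a pathway passes when its score −log₁₀ *p*
  exceeds 2 and it contains more than 5 disease genes.  For every pair of
  enriched pathways a 2×2 table (*n*, *N − n*, *r*, *R − r*) compares the
  pair's shared genes (and shared PPI edges) against the across-pairs
  averages *r*, *R*; node and link p-value vectors are Benjamini–Hochberg
  adjusted and a pair has crosstalk when min(*p*<sub>nodes</sub>,
  *p*<sub>links</sub>) < 0.01.
* **GWAS prioritization.** Genes with *p* < 0.05 in both of two independent
  studies are "joint significant"; enrichment of the subnetwork for joint
  signals is tested by drawing 1,000 equally sized random gene sets from the
  genes common to both studies (10 repeats with derived seeds).  Novel
  candidates are joint-significant subnetwork genes outside the seed list,
  each reported with its ego subnetwork; a pathway-guided route extracts a
  pathway's Steiner subnetwork and ranks its non-seed connectors by degree.

## Worked example

```r
library(dgnet)

cfg <- synthetic_config(n_nodes = 2000, master_seed = 42)
fix <- generate_fixture(cfg)
fix
#> <synthetic_fixture> 2000 nodes, 6257 edges; 5 gene sets; 12 pathways; disease subnetwork 218 nodes

ts <- summarize_topology(fix$network, fix$gene_sets$disease_like)
ts
#> <topology_summary>disease_like
#>  mapped genes:      160 (0 unmapped)
#>  average degree:    10.46
#>  mean char. SPD:    3.54
#>  mean glob. centr.: 3.42
#>  hub cutoff / frac: 8 / 0.356

resample_empirical_p(fix$network, "average_degree", ts$average_degree,
                     ts$n_mapped, "greater", n_reps = 1000, seed = 7)
#> <empirical_test> average_degree observed=10.46 p=0 (0/1000, direction=greater, seed=7)

fix$disease_subnet
#> <steiner_result> 218 nodes, 404 edges; 160 terminals, 58 Steiner nodes, 0 unreachable

clique_percolation(fix$disease_subnet$subnetwork, 3)
#> <community_set> k = 3 - 2 communities from 101 k-cliques covering 56 nodes

nonrandomness_test(fix$disease_subnet$subnetwork, n_reps = 1000, seed = 7)
#>                   metric observed null_mean null_sd n_greater n_less direction empirical_p
#> 1         average_degree   3.7064     3.706  0.0000         0      0   greater           0
#> 2            average_spd   3.6392     4.175  0.0554      1000      0 two-sided           0
#> 3 clustering_coefficient   0.0631     0.015  0.0064         0   1000   greater           0
```

Reading the output: the disease-like set's average degree (10.46) is higher
than every one of 1,000 random 160-gene sets (*p* = 0, hub-biased planting
recovered); the Steiner subnetwork nets all 160 seed genes through 58
connector proteins; its mean clustering coefficient (0.063) exceeds all
1,000 matched random graphs (*p* = 0), i.e. the subnetwork is decidedly
non-random, while its shortest paths are shorter than random (hub-mediated).

The same stages run end-to-end from one configuration:

```r
run_pipeline(pipeline_config(synthetic = synthetic_config(), seed = 1),
             outdir = "dgnet_out")
```

which writes TSV/GraphML artifacts per stage plus a machine-readable
`report.json`, and is byte-identical across reruns with the same seed.  A
thin command-line wrapper lives at `inst/cli/pipeline.R`.

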