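# netscreen

Topological hub screening for network pharmacology.

Multi-herb remedies act on many proteins at once, so their mechanism is
better described as a perturbation of a molecular interaction network than
as a single drug–target pair. `netscreen` implements the standard screening
pipeline for this setting: assemble a network from the remedy's putative
targets, the disease's known therapeutic targets and a merged
protein–protein interaction (PPI) union; rank every protein by four
topological parameters; keep the "major hubs"; check that the selection
reflects real structure with a random-graph null; and test the major hubs
for pathway over-representation. It is written for computational biologists
reproducing or extending herb–target–disease analyses from pre-exported
database tables (TSV/CSV, GMT), with no live database queries.

## The screen

With the network as a simple undirected graph on $n$ nodes:

* **Hubs** — node $i$ is a hub when $\deg(i) > 2\,\mathrm{median}(\deg)$
  (strict). On sparse PPI unions the median degree is 1, so the cutoff is 2.
* **Major hubs** — on the *hub-induced subnetwork*, compute degree,
  betweenness $b(i)=\sum_{s<t}\sigma_{st}(i)/\sigma_{st}$ (normalized by
  $\binom{n-1}{2}$), closeness (component-restricted, Wasserman–Faust
  scaled: $\frac{r-1}{n-1}\cdot\frac{r-1}{\sum_j d(i,j)}$ for a component
  of size $r$), and coreness (k-core shell index). A hub is a major hub
  when it strictly exceeds all four thresholds — the medians of the
  hub-subnetwork metrics by default, or explicit cutoffs such as the
  `zjwThresholds()` preset (degree > 4, betweenness > 0.0002,
  closeness > 0.3919, coreness > 5).
* **Null model** — Erdős–Rényi $G(n,m)$ counterparts conserve the node set
  and edge count, rewire uniformly, and are screened with the same policy;
  the report gives the replicate distribution of major-hub counts and the
  empirical exceedance of the real count.
* **Enrichment** — hypergeometric upper tail $P(X \ge k)$ for a query of
  $n$ ids against each pathway ($K$ members in a universe of $N$), with
  Benjamini–Hochberg q-values.

A synthetic generator (`syntheticConfig()` / `generateStudyFixture()`)
produces study-shaped fixtures — a 5559-node / 21567-edge scale-free PPI
with median degree 1, herb target sets of 175 and 348 sharing 106, 90
disease targets, and planted hubs/pathways with ground truth — so the whole
pipeline is testable without any downloads.

## Worked example

```r
library(netscreen)

sim <- simulateStudyData(syntheticConfig(seed = 1), "demo")
report <- runPipeline(c(sim$config, list(null_replicates = 100)))

report$network$nNodes        # 5559
report$network$nEdges        # 21567
report$network$medianDegree  # 1     -> twofold-median hub cutoff is 2
report$screen$nHubs          # 2216  nodes with degree > 2
report$screen$nMajorHubs     # 617   hubs above all four metric medians
report$null$replicateMedian  # 0     major hubs in a typical G(n,m) replicate
report$null$exceedance       # 0     no replicate reaches the real count
report$enrichment$nSignificant  # 5  pathways with BH q < 0.05
```

The contrast in the last four numbers is the point of the method: the real
network concentrates topological importance in a few hundred proteins,
while a degree-preserving-in-count-only random rewiring concentrates it in
(essentially) none, and the major hubs recover exactly the five pathways
whose enrichment was planted in the generator. `demo/results/` additionally
holds the network (GraphML), the per-node screen table, the per-replicate
null counts and the enrichment table as TSV, plus `report.json`.

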