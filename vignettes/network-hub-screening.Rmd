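---
title: "Screening interaction networks for major hubs: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening interaction networks for major hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`netscreen` implements a two-stage topological screen for
network-pharmacology studies, together with the scaffolding such a study
needs: table ingest, network assembly, an Erdős–Rényi null contrast,
hypergeometric pathway over-representation, and a synthetic study generator
with planted ground truth. This vignette is the package's account of the
science: the procedure and its assumptions, the parameters that matter,
what the generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## The screening model

The object being screened is a simple undirected graph whose nodes are
proteins of three provenances: *putative* targets of the remedy (predicted
compound–protein interactions), *known therapeutic* targets of the disease
(drug databases, disease-genetics catalogues), and *linker* proteins that
connect them in the PPI. Nodes in both target sets are labelled *both*; the
four labels partition the node set.

**Stage 1 (hubs).** A node is a hub when its degree strictly exceeds
`hubFactor` (default 2) times the median degree of *all* nodes. Sparse PPI
unions have median degree 1 — half the proteins are picked up by a single
interaction — so the cutoff is 2 and the stage removes nodes of degree
≤ 2. The strict inequality matters: "degree ≤ twice-median is removed" and
"degree > twice-median is kept" are the same rule only when the inequality
is strict on the keep side.

**Stage 2 (major hubs).** The vertex-induced subnetwork on the hubs — the
direct interactions among hubs — is profiled with four parameters:

* *degree*: number of links;
* *betweenness*: fraction-weighted count of shortest paths through the
  node (endpoints excluded), normalized by $(n-1)(n-2)/2$;
* *closeness*: inverse summed distance to the other nodes (conventions
  below);
* *coreness*: the k-core shell index, i.e. the largest $k$ such that the
  node survives the iterative removal of all nodes of degree < $k$.

A hub whose four values all strictly exceed their thresholds is a major
hub. Under the default `median_derived` policy the thresholds are the
medians of the four metrics over the hub subnetwork itself; an `explicit`
policy accepts fixed cutoffs, and `zjwThresholds()` provides the reference
preset (degree > 4, betweenness > 0.0002, closeness > 0.3919,
coreness > 5) used in the Zuojin Wan gastritis screen that this pipeline
generalizes.

The crucial, easily-missed convention is that stage 2 is computed **on the
hub subnetwork**, not the full network: the profile records which graph it
was computed on (`scope`), and `screenHubs()` wires the two stages
together so the thresholds and the metrics always refer to the same graph.

## Conventions behind the numbers

Published threshold values are meaningless without the normalization
conventions, which are rarely stated. The package fixes them as follows
and treats alternatives as options, not errors:

* **Betweenness** is normalized to $[0,1]$ by the interior pair count
  $(n-1)(n-2)/2$; graphs with fewer than three nodes have no interior
  pairs and return zeros. A reference cutoff of 0.0002 is only consistent
  with normalized values on a graph of a few thousand nodes, which is why
  normalization is the default.
* **Closeness on disconnected graphs** uses the component-restricted form
  with Wasserman–Faust scaling: for node $i$ in a component of size $r$,
  $\frac{r-1}{n-1}\cdot\frac{r-1}{\sum_{j} d(i,j)}$. This is bounded in
  $[0,1]$, reduces to ordinary normalized closeness when the graph is
  connected, makes values comparable across components of different sizes,
  and sends isolated nodes to 0. Harmonic closeness is available via
  `computeCloseness(x, rule = "harmonic")` for sensitivity analysis, since
  the convention behind any particular published cutoff is unknowable.
* **Medians with even counts** are the mean of the two central order
  statistics (R's default). Combined with strict `>`, an all-equal metric
  empties the filter — a real degeneracy discussed below, not a bug.
* **Ties** need no breaking anywhere in the screen: the filters are
  deterministic set comprehensions.
* Centralities are floating-point; tests compare them to independent
  oracles at 1e-9.

## Network assembly and its main uncertainty

`buildInteractionNetwork()` seeds the graph with putative ∪ disease
targets and expands over the merged PPI. Which "interactional" proteins to
admit is the main reconstruction uncertainty in this family of studies,
and it is exposed as an explicit parameter:

* `first_neighbor` (default for real data): seeds plus every direct PPI
  partner of a seed, with all edges among the admitted nodes. The smallest
  rule that produces linker nodes.
* `seed_only`: no expansion; only edges among seeds survive.
* `full_ppi`: the whole merged PPI plus any isolated seeds.

Isolated seeds are always retained as degree-0 nodes — they are removed by
the degree filter anyway, and keeping them makes target accounting exact.
The network is deliberately *not* reduced to its largest component;
component handling is deferred to the closeness convention.

## The null model

The null conserves the node set and the number of links and rewires
uniformly at random — $G(n,m)$ sampling, i.e. a uniform draw from all
simple graphs with exactly those counts. Degree-preserving edge swaps are
deliberately **not** offered: the contrast being made is against
structure-free wiring, not against degree-sequence-preserving wiring, and
conflating the two would change the claim. `nullScreen()` re-runs the full
two-stage screen on each replicate — re-deriving medians per replicate
under the median policy, reusing fixed cutoffs under the explicit policy —
and reports per-replicate major-hub counts plus the empirical exceedance
(fraction of replicates reaching the real count). Multi-replicate
exceedance is an extension over single-null-network practice and is
labelled as such in the report. On study-shaped inputs the replicate
median is 0: random wiring at mean degree ~8 produces a degree
distribution so homogeneous that almost nothing passes the twofold-median
cut, which is precisely the point of the contrast.

## Enrichment

`enrich()` is a transparent hypergeometric over-representation test:
$p = P(X \ge k)$ for an overlap of $k$ between the query (normally the
major hubs) and a pathway of $K$ members, in a universe of $N$. The
default universe is the profiled network's nodes intersected with the
annotation; the annotation's own universe or a user background are
options, and the universe used is recorded in every result. Raw p-values
with a strict `p < 0.05` filter reproduce common practice; the package
also computes Benjamini–Hochberg q-values and defaults to filtering on
them, since 50+ pathways are typically tested. Functional "module"
grouping of significant pathways is mechanized via an explicit
user-supplied category map (`assignModules()`) rather than guessed from
pathway names.

## What the synthetic generator emulates

`syntheticConfig()` defaults encode the study conditions the pipeline is
validated under: a PPI union of 5559 proteins and 21567 interactions with
median degree 1 (so the hub cutoff is 2), herb target sets of 175 and 348
with exactly 106 shared, 90 disease targets arriving as a 75-row
drug-database table plus a 15-row disease-genetics table, 30 planted hubs,
and 50 pathways of 20–80 members (typical curated pathway-map sizes) of
which 5 are planted.

The graph generator anchors topology with a preferential-attachment tree,
then attaches the remaining edges preferentially (weight
$\deg^\alpha$, $\alpha$ = `attachmentExponent`, default 1) **among
internal nodes only**. Keeping pendant leaves pendant is what pins the
median degree at 1; the preferential extras among internal nodes produce
the heavy tail and a dense core. Planted hubs are then wired to
`plantedHubDegree` (default 60) partners drawn with probability
proportional to degree — degree-weighted rather than uniform, because a
"planted hub" wired to random leaves would lose its neighbors at the
hub-subnetwork step and carry no coreness or closeness signal, making the
ground-truth label meaningless for the screen being tested. The edge count
is then restored exactly by deleting edges between two non-planted
low-degree nodes (never reducing a node below degree 1), so the handshake
lemma and the configured $m$ hold for every seed. Planted pathways draw
their in-neighborhood members degree-weighted for the same reason: the
planted signal is enrichment among high-centrality nodes.

Because the generator emulates the *already-assembled* study network —
its nodes are exactly the targets and their interactors — the simulated
pipeline configuration uses the `full_ppi` expansion; running
`first_neighbor` closure on it would re-densify the graph (median degree
9 instead of 1) and screen a different object than the one generated.

What the generator does **not** emulate: identifier noise and cross-
database synonym collisions, confidence-scored or directed edges,
compound–target prediction error (targets are drawn from the true node
set), correlated pathway membership, and any chemistry (no structures,
ADME, or binding affinities). Passing tests therefore demonstrate that the
screen recovers planted topological and enrichment signal under clean
identifiers and unweighted edges — not that any particular biological
conclusion from real exports is correct.

A degeneracy worth knowing about: in small or homogeneous graphs the hub
subnetwork's main core can contain more than half the hubs, making the
median coreness equal its maximum; the strict filter then returns zero
major hubs. This is faithful behavior of the median+strict rule, observed
here for sub-1000-node versions of the default shape (the test fixtures
use a slightly steeper attachment exponent, 1.2, to keep the k-core
hierarchy graded at that scale). At the default 5559-node shape the screen
produced 269–780 major hubs with 100% planted-hub recovery over 20
consecutive seeds.

## Reproducibility and problem sizes

All generator randomness flows from the single `seed` field (sub-stages
derive fixed offsets from it); `nullScreen()` draws its per-replicate
seeds from `baseSeed`; identical configurations produce byte-identical
serialized fixtures and identical pipeline reports. The validation suite
checks the four metrics against brute-force oracles (adjacency-matrix
power counting for paths, explicit pruning for coreness) exhaustively on
all 771 connected labeled graphs with up to 5 nodes, on a seeded sample of
3000 of the 26704 connected labeled graphs on 6 nodes, and on 200 seeded
random graphs of up to 30 nodes; the enrichment p-value is checked against
full enumeration of all $\binom{N}{n}$ draws for universes up to 15 and
against the one-sided Fisher exact test on random tables. End-to-end
validation uses the full 5559-node shape: 100 null replicates and 20
independent seeds for planted-structure recovery. These sizes were chosen
to keep the complete suite under a few minutes while leaving the
study-scale behavior, not a toy, as the thing being tested.

## Known limitations

* Identifiers are opaque strings (trimmed, upper-cased); real studies
  need an external mapping to one namespace, supported only via a
  user-supplied two-column table.
* The ingest readers accept TSV/CSV, not spreadsheets; export
  spreadsheets to TSV first.
* Betweenness/closeness conventions differ across published tools; when
  comparing against published explicit cutoffs, treat them as presets to
  be sensitivity-checked (both threshold modes are first-class for this
  reason).
* The enrichment test is the plain hypergeometric; no ranked (GSEA-style)
  or topology-weighted variants.
* $G(n,m)$ is the only null; configuration-model nulls are out of scope.
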