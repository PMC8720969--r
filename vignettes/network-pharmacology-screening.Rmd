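---
title: "Network-pharmacology screening with herbnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-pharmacology screening with herbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The inference chain

Multi-herb formulae act through many weak component-target interactions at
once, and the standard way to dissect such a system is a screening cascade
rather than a single model fit. `herbnet` implements that cascade as eight
composable stages:

1. **ADME filter.** Candidate components are kept when oral bioavailability
   and drug-likeness clear `OB >= 30` (percent) and `DL >= 0.18`
   (unitless). Both cuts are inclusive: the conventional phrasing of the
   screen is "greater than or equal", and the thresholds themselves are
   tunable (`filterComponents()`).
2. **Differential expression.** Two-group log2 expression is summarized per
   gene by `log2FC = mean(case) - mean(control)` and a two-sided Welch
   t-test, with Benjamini-Hochberg control across genes. A gene is a DEG
   when `|log2FC| > 1` **and** `q < 0.05`, both strict, so a gene sitting
   exactly on a threshold is not called.
3. **Target intersection.** The targets of the surviving components are
   intersected with the DEG set; the common targets and the
   component-target bipartite network summarize which molecules hit the
   disease transcriptome (`commonTargets()`, `buildBipartite()`).
4. **Enrichment.** Over-representation of the common targets in a gene-set
   collection uses the upper-tail hypergeometric probability
   `P(X >= k)` with universe size `N`, set size `K`, query size `n` and
   overlap `k`, BH-adjusted *within each category* (BP/CC/MF/KEGG), because
   top-term reporting is conventionally per category. A preranked GSEA
   (`gseaPreranked()`) is available for phenotype-association analyses of
   individual gene sets.
5. **PPI screening, stage 1.** On the interaction network, nodes with
   degree strictly above twice the median degree are kept (the
   double-median-degree rule); a fixed absolute cut-off is supported for
   reproducing published configurations.
6. **PPI screening, stage 2.** Degree and betweenness are *recomputed on
   the subnetwork* and nodes must exceed both `dc_min` and `bc_min`
   strictly. Recomputing stage-wise matches how interactive network tools
   behave; reusing the original-network values would conflate the two
   stages.
7. **Hub selection.** Hubs are the triple intersection of the screened core
   network, the component-target set and the disease-pathway genes
   (`selectHubs()`), with per-symbol provenance.
8. **Coexpression and docking.** Hub-indicator coexpression is Pearson's r
   with the t-transform p-value (n - 2 df), flagged by `r > 0.3` and
   `p < 0.05`; externally produced docking tables are thresholded at
   `energy <= -5 kcal/mol` (inclusive) and, when a hydrogen-bond column
   exists, `>= 2` H-bonds, then ranked by energy or interaction count.

All stage thresholds live in one flat configuration (`herbnetConfig()`)
whose defaults are exactly the values above; nothing is hard-coded inside a
stage.

## Betweenness and closeness conventions

Centrality conventions vary enough across tools to change screening
results, so `herbnet` fixes them explicitly (`computeCentralities()`):

* **DC** is the plain degree.
* **BC** is unnormalized shortest-path betweenness with each unordered pair
  counted once, equal-length paths split evenly and endpoints excluded
  (Brandes accumulation). On a ~900-node subnetwork this convention
  produces values on the scale of published cut-offs in the hundreds.
* **CC** is closeness within the connected component,
  `reachable / sum(distances)`; isolated nodes get `NA`. Closeness is
  reported but not used as a filter: the screening literature names DC and
  BC thresholds, and where figure captions also mention CC the method text
  does not give a threshold for it, so `herbnet` surfaces CC without
  filtering on it.

## Relative screening thresholds

Published absolute cut-offs (e.g. `DC > 60`, `BC > 645`) are tied to the
size of the interactome they were derived on and do not transfer to the
desk-scale graphs the synthetic generators produce. `coreScreen()`
therefore accepts `NULL` thresholds meaning: reapply the
double-median-degree rule on the subnetwork (`DC > 2 x median`) and require
`BC > 0` (the node must lie on at least one shortest path). The BC
component is deliberately permissive: a planted dense core behaves like a
clique, and clique interiors carry *low* betweenness because their pairwise
distances are 1, so a median-BC cut would preferentially discard exactly
the nodes the screen is meant to find. With the relative rule the cascade
recovers planted cores with recall ~1.0 and precision above 0.8 across
seeds at the default generator settings.

## What the synthetic generators emulate

Every pipeline input has a generator with a ground-truth ledger
(`SyntheticTruth`), and one integer seed drives a dedicated RNG stream per
generator, so adding a generator never perturbs the draws of another.

* `simulateComponents()` draws ADME properties such that an exact planted
  subset passes the OB/DL screen, with passing rows strictly above both
  thresholds. Supports are wide enough to represent the reported spread of
  pivotal flavonoids (DL up to 0.45, OB 30.5-70%).
* `simulateExpression()` is microarray-like: Gaussian log2 values around
  gene-specific baselines (`N(7, 1.5^2)`), within-group SD `sigma = 0.5`,
  and mean shifts of `±lfc` planted in the case group, half up and half
  down. The default design is 30 cases versus 9 controls, the emulated
  cohort's shape. Count-based (negative-binomial) noise is deliberately not
  modeled, because the screening chain operates on processed expression.
* `simulatePPI()` grows a preferential-attachment background (`m = 2`
  edges per node) and plants a dense core (`coreP = 0.8` internal edge
  probability, each core node also anchored into the background) - the
  minimal structure that makes a centrality cascade meaningful.
* `simulateGeneSets()` plants over-representation by drawing at least 60%
  of an enriched set's members from a planted list.
* `simulateCoexpression()` draws bivariate-normal pairs with exact target
  correlations.

`simulateStudy()` wires these together coherently (core nodes are DE,
targeted by passing components and seed the enriched sets) so the planted
core should re-emerge as the hub set after all eight stages.

What passing these tests does **not** show: real expression data have
correlated genes, batch effects and heavy-tailed noise; real interactomes
have study bias in their degree distribution; real annotation collections
are hierarchical and redundant. The synthetic suite validates the
*mechanics and calibration* of the chain, not its behavior under those
real-data pathologies.

## Numerical and design choices

* **DEG test.** A Welch t-test per gene, vectorized, rather than a
  moderated-t model: it is assumption-light, dependency-free and exact
  under the generator's Gaussian model. The contract (`gene -> raw p`) is
  narrow enough that a moderated backend can be swapped in. Degenerate
  genes follow fixed conventions: zero variance in both groups gives
  `p = 1` for equal means and `p = 0` (with a warning) otherwise.
* **ORA universe.** Defaults to the union of the collection's members when
  not supplied. This is the single largest driver of differences between
  ORA implementations; supply an explicit universe for comparisons.
* **GSEA null.** Gene-label permutation (the interface is a preranked
  list, so phenotype permutation is unavailable). The nominal p uses the
  add-one estimator within the sign-matched half of the null,
  `(b + 1) / (n_same + 1)`, which is never zero and calibrates to a
  roughly uniform null; NES divides ES by the mean |ES| of that same half.
* **Tie-breaking.** Every ranking in the package is a total order:
  DL ranking breaks ties by OB then mol id; DEG ranking by q, raw p,
  |log2FC|, symbol; target degree and docking rankings fall back to
  lexicographic order. This makes artifacts byte-reproducible.
* **Strict versus inclusive cuts.** Expression and centrality thresholds
  are strict (`>`, `<`); the ADME screen and the docking energy ceiling
  are inclusive (`>=`, `<=`), following the conventional phrasings of each.
* **Symbols.** Uppercased and whitespace-trimmed on ingest everywhere; no
  alias dictionary is consulted.

## Problem sizes

The validation suite runs at deliberately modest scales - 600-node
backgrounds with 30-node cores, 2,000-gene expression matrices, 15-40
member gene sets over 400-gene universes, betweenness oracles on graphs of
at most 12 nodes and exhaustive hypergeometric enumeration up to `N = 25` -
sizes at which independent brute-force oracles are exact and fast while
the planted structure still dominates sampling noise.

## Known limitations

* The package consumes edge lists, expression matrices and docking tables;
  it does not query the upstream databases those artifacts come from, and
  identifier harmonization beyond case-normalization is out of scope.
* Headline counts of any particular published analysis (numbers of
  components, targets, DEGs, network sizes) depend on database snapshots
  and are not reproducible from the shipped code; the package reproduces
  the *rules* and the printed tables, and validates the rules on planted
  ground truth.
* Betweenness is exact, not sampled; networks far beyond 10^4 nodes will
  want an approximate backend.
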