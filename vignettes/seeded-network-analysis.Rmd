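---
title: "Seeded neighbor networks, MCODE modules, and expression overlay"
author: "MGNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded neighbor networks, MCODE modules, and expression overlay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MGNet)
```

## The analysis

Membranous glomerulonephritis (MGN) is an immune-mediated kidney disease.
MGNet studies how immune-annotated genes and MGN-associated genes relate
inside the human protein–protein interaction (PPI) network, in four steps:

1. **Seeded neighborhoods.** From a base PPI graph and two seed lists
   (immune genes, disease genes), `buildNeighborNetwork()` extracts the
   *induced* subgraph on the seeds present in the base plus their direct
   interactors. Applied with the union of both lists this yields the
   immune-or-MGN-directed neighbor network (IOMDN); applied again *inside*
   the IOMDN with the disease genes alone it yields the nested MGN-directed
   network (MGND). The induced rule — edges between two non-seed neighbors
   are kept — matters: dense modules routinely contain edges among
   non-seed genes, which a star-only extraction would discard. A
   sensitivity flag is not needed for the nested construction because
   `buildNeighborNetwork()` accepts any base network, so extraction of the
   MGND directly from the full PPI is a one-line variant.
2. **Topology.** `topologySummary()` reports density
   $2E/(N(N-1))$, mean degree $2E/N$, and the average local clustering
   coefficient; `degreeDistribution()` adds a descriptive ordinary
   least-squares fit of $\log_{10} N(k)$ on $\log_{10} k$;
   `hubAnalysis()` stratifies degrees by the four-way node classification
   (both / disease-only / immune-only / other).
3. **Dense modules.** `detectModules()` is a from-scratch MCODE:
   k-core-based vertex weighting, greedy seeded expansion, and
   post-processing, with the standard defaults.
4. **Expression overlay and enrichment.** `correlateEdges()` computes
   edge-wise Pearson correlations on disease samples with two-sided
   significance; `differentialExpression()` runs unpaired t-tests between
   disease and control samples; `overrepresent()` replaces web-service
   enrichment with a local hypergeometric test over user-supplied GMT
   collections.

`runPipeline()` drives all stages from one configuration and writes a
deterministic JSON report plus TSV artifacts.

## MCODE: algorithmic choices

The module detector follows the published MCODE procedure. For a vertex
$v$ with degree at least `degreeCutoff` (default 2), the weight is
$k \cdot \mathrm{density}(C)$ where $C$ is the highest k-core of the
closed neighborhood $N[v]$ and $k$ its core number. Complex prediction
seeds at the highest-weight unvisited vertex and admits, breadth-first up
to `maxDepth` (default 100), unvisited neighbors with weight strictly
greater than $w_{seed}(1 - \texttt{nodeScoreCutoff})$ (cutoff 0.2).
Candidates lacking a 2-core are discarded; `haircut` (on by default)
iteratively strips vertices with fewer than two intra-module connections;
`fluff` (off by default) may add boundary vertices with closed-neighborhood
density above `fluffDensityCutoff`, and only fluffed vertices may be shared
between modules. Modules are scored density × size.

Two points were genuinely open and are resolved as follows:

* **Tie-breaking.** MCODE leaves seed and expansion ties unspecified. All
  ties here are broken by lexicographic gene symbol, and networks store
  nodes and canonical edges sorted, so output is invariant to input
  ordering — a property the test suite asserts by permuting edge input.
* **Two rankings.** The complex set is returned in the tool's native
  score order; `rankModules()` separately implements ranking by node
  count (the extraction rule used for reporting top-N modules), with
  score and then smallest member symbol as tie-breaks. The two orders can
  disagree: node-count ranking may promote a large sparse complex above a
  small dense one. Recovery statements about detection quality therefore
  refer to the top-*scoring* module.

A consequence of the published expansion rule worth knowing: on a pure
cycle every vertex has the same weight, the threshold
$0.8\,w_{seed}$ admits every neighbor, and the entire cycle — which is a
2-core — is reported as a single low-density module. Degenerate regular
graphs are absorbed rather than rejected; the score (≈ 2 for a long
cycle) keeps such modules at the bottom of the score ranking.

## Statistical conventions

* **Edge correlation significance** uses the t transform
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, which is the
  exact null distribution under bivariate normality. With $n = 21$ disease
  samples this gives $p = 4.1\times10^{-4}$ at $r = -0.70$ and
  $p = 0.028$ at $r = -0.48$. Edges are *significant* at two-sided
  $p < 0.05$ (configurable) and *strong* when $|r| > 0.5$; the strong rule
  uses the absolute value because correlations of $-0.7$ clearly belong to
  the "strong" class. Correlations are computed on disease samples by
  default (`group = "all"` is available for sensitivity analysis), over
  pairwise-complete observations, with the per-edge $n$ recorded.
* **Differential expression** defaults to Welch's unpaired t-test —
  robust to unequal group variances at 21 vs 18 samples — with the
  equal-variance Student variant available. The *differential* flag uses
  the raw p-value at $\alpha = 0.05$ because the analysis this package
  operationalizes works with unadjusted p-values; Benjamini–Hochberg
  q-values are always computed and written alongside, clearly labeled, so
  an adjusted analysis costs one column selection.
* **Over-representation** is the hypergeometric upper tail
  $P(X \ge k)$ with BH adjustment across terms and an enrichment cutoff
  of raw $p < 0.01$. The default background is the gene set of the
  analyzed network — the sampling frame from which module genes were
  actually drawn — rather than the collection's union, which is
  configurable for sensitivity to background choice.
* **Degenerate inputs.** Zero-variance genes on an edge invalidate that
  edge's record (excluded from summaries, never silently zero); $|r| = 1$
  is flagged degenerate with the p-value floored at the smallest
  representable positive number; genes with fewer than three observations
  in a group are skipped with a warning; density of a graph with fewer
  than two nodes is reported as 0 with a warning.

## The synthetic benchmark

`scenarioConfig()` fixes the benchmark conditions: a 500-node
preferential-attachment background (2 edges per arriving node), one
planted 12-node module whose internal density is raised to 0.9 by edge
addition, 15 disease and 60 immune seeds placed so that 3 disease and 6
immune seeds fall inside the planted module (half of the disease seeds are
also immune, producing the BOTH category), 21 disease and 18 control
samples, planted edge correlations of magnitude 0.7 (one quarter
negative), and differential effect $d = 1.5$. Sample sizes mirror the
clinical dataset the analysis is designed for; the correlation and effect
sizes are set so that the tests' power at those sample sizes exceeds
0.9/0.95, which makes recovery assertions statistically stable; the
background size keeps a full pipeline run around one second.

Expression follows a latent-factor model: module members get
$x_g = \mu_g + \beta_g f_s + \varepsilon$, with one factor $f_s$ per
module and per sample and $\varepsilon \sim N(0, \sigma^2)$. Loadings are
sized so the implied pairwise correlation
$\beta_g\beta_h/\sqrt{(\beta_g^2+\sigma^2)(\beta_h^2+\sigma^2)}$ has
magnitude 0.7, with the sign given by the loading signs. This
construction was chosen over direct multivariate sampling because it
scales to any module size, is positive-definite by construction, and
yields a closed-form implied correlation that tests verify empirically.
Planted differential genes receive a mean shift of $d$ times their total
standard deviation on the disease samples.

What the generator deliberately does **not** emulate: probe-level
artifacts, batch structure, heavy-tailed microarray noise, and the
specific topology of curated interaction databases. Passing recovery
tests therefore demonstrate correctness of the algorithms under their own
statistical assumptions, not performance on any particular database
snapshot — headline counts from such snapshots (node totals, retention
percentages, module tallies) are reproducible only from the user's own
input files, which the pipeline report emits side by side for that
purpose.

Recovery of the planted module is intentionally assessed as a *mean*
Jaccard over 20 seeded replicates (threshold 0.8). Per-replicate overlap
fluctuates between about 0.67 and 1: members whose internal connectivity
sits below the module average can fall under the expansion threshold
$0.8\,w_{seed}$ and be trimmed, which is faithful MCODE behavior, not a
defect of the generator.

## Problem sizes used by the test suite

The suite exercises exhaustive oracles on graphs of up to 15 nodes
(pair/triple counting for density and clustering, subset enumeration for
the highest k-core, draw enumeration for the hypergeometric tail at
backgrounds up to 12), calibration at 1000 null edges and 2000 null genes,
power at 500 planted pairs/genes, and module recovery on twenty 500-node
replicates — sizes chosen so the full suite completes in well under a
minute while keeping Monte-Carlo error far from the asserted margins.

## Known limitations

* Gene identity is the uppercased symbol string; no alias or identifier
  mapping is attempted, so seed lists and networks must share a symbol
  vocabulary.
* The degree-distribution fit is descriptive OLS on the log-log
  histogram, suitable for the qualitative "scale-free" statement, not a
  maximum-likelihood exponent estimate.
* Isolated nodes are included in mean clustering (as 0) and density
  denominators; analyses that drop isolates will report slightly
  different averages.
* `correlateEdges()` requires unique gene rownames and at least four
  samples in the chosen group; collapse probes first.
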