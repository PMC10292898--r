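---
title: "Network proximity screening for drug repurposing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network proximity screening for drug repurposing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netRepurpose)
```

## The screening problem

Natural products and multi-compound preparations act through many targets at
once. A practical way to ask whether one of their constituent compounds is a
plausible candidate for a disease is to place both the compound's protein
targets and the disease's proteins on the human protein--protein interactome
and measure how the two sets relate topologically. `netRepurpose` implements
that screen as a reusable chain:

1. **Interactome assembly** — merge edge lists into one undirected,
   unweighted graph with canonical node IDs, no self-loops and no duplicate
   edges.
2. **Target-set similarity** — pairwise Jaccard indices between compound
   target sets, summarizing how much independent information the compounds
   carry.
3. **Module significance** — the size of the largest connected component
   (LCC) induced by a compound's targets, against a degree-preserving null.
4. **Network proximity** — closest/shortest distances between compound
   targets and disease proteins, z-scored against the same null, with
   top-$k$ ranking.
5. **ROC validation** — does proximity separate known therapeutic
   compound--disease pairs from unconnected ones?
6. **Expression follow-up** — differential expression between case and
   control samples, intersection of DEGs with the screened compounds'
   targets, degree-ranked hub targets, and per-gene diagnostic ROC cutoffs.

## The statistics

All distances are unweighted hop counts $d(s,t)$ on the interactome. For a
compound target set $S$ and disease protein set $T$:

* closest distance: $d_c(S,T) = \frac{1}{|T|}\sum_{t \in T} \min_{s \in S} d(s,t)$
* shortest distance: the mean of $d(s,t)$ over all pairs.

Both are z-scored against a null in which $S$ is replaced by a random,
degree-matched node set (the disease set stays fixed):
$z = (d_{obs} - \mu_{null})/\sigma_{null}$, with $\mu$ and $\sigma$ the mean
and sample standard deviation over `nReps` replicates (default 1000).
Negative $z$ means *closer than degree-matched chance*. The LCC statistic is
z-scored the same way, with replicate value = the largest component induced
by the random set; the screening rule is $|z| > 1.70$.

**Degree-matched sampling.** Scale-free interactomes have a few hubs whose
short distances to everything would dominate any uniform null. Nodes are
therefore partitioned into degree bins (greedy accumulation from the lowest
degree until a bin holds at least `minBinSize = 100` nodes; an undersized
remainder merges downward) and each replicate draws, within every bin,
exactly as many nodes as the observed target set has there, uniformly
without replacement. Only the compound side is randomized; randomizing the
disease set as well would answer a different question (whether this disease
is special among diseases) than the screen asks (whether this compound is
special among degree-matched pseudo-compounds).

**ROC.** AUC is computed by pair counting (Mann--Whitney; ties count 0.5)
and the curve by a threshold sweep with a "$\ge$ threshold is positive"
rule. Pair scores are $-z_c$, so higher means more plausibly therapeutic.
Two AUCs are compared by stratified bootstrap: positives and negatives of
each set are resampled independently 2000 times and the two-sided p-value
is the smoothed percentile probability that the AUC difference crosses
zero. This choice is assumption-light, reproducible under a seed, and holds
its nominal size (the test suite measures the type-I error at
$\alpha = 0.05$ over 500 null simulations and requires $5\% \pm 2\%$).

**Differential expression.** Per-gene Welch two-sample $t$-tests on
log2-scale values, Benjamini--Hochberg adjustment across all genes, and
strict thresholds $|\text{logFC}| > 0.5$ and adjusted $p < 0.05$, with
logFC defined as case minus control (orientation recorded in the output).
A moderated-variance model would borrow strength across genes; at the
26 + 26 design this package targets, the Welch test is asymptotically
equivalent and keeps the stage self-contained. Genes constant in both
groups get $p = 1$ when the means agree and $p = 0$ otherwise.

**Diagnostic ROC.** A gene's expression is used directly as a classifier
score; orientation is chosen so AUC $\ge 0.5$ and recorded as `up` or
`down`. The cutoff maximizes Youden's $J$ over the observed expression
values, with $J$-ties broken toward higher specificity; AUC $> 0.9$ flags a
high-accuracy biomarker. Cutoffs are reported on the input expression scale.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `nReps` | 1000 | null replicates behind every z-score; the Monte-Carlo SE of $z$ scales as $\sqrt{(1+z^2/2)/n}$ |
| `minBinSize` | 100 | minimum degree-bin occupancy; prevents near-deterministic resampling of hubs |
| `zThreshold` | 1.70 | LCC screening threshold on $|z|$ |
| `lfcThresh`, `alpha` | 0.5, 0.05 | strict DEG thresholds on log2 fold change and BH-adjusted p |
| `kTopCompounds` | 8 | compounds kept by the proximity ranking (sorted by $z_c$, ties by $d_c$, then name) |
| `kHubs` | 12 | hub targets selected by induced-subgraph degree (ties alphabetical) |
| `minTargets` | 2 | minimum mapped targets for an LCC to be evaluable; a connected component needs two nodes, so compounds with fewer are flagged `not_evaluated` rather than scored |

## Numerical and degenerate-input conventions

* All proximity and LCC analyses run on the interactome's largest connected
  component (`analysisComponent()`), because unreachable pairs make the
  distance means undefined; dropped nodes are counted in the load report,
  and any remaining unreachable disease proteins are excluded with a
  warning.
* A zero-variance null ($\sigma = 0$) yields $z = 0$ when the observed
  statistic equals the null mean and a signed infinity otherwise, flagged
  `degenerate_null` (e.g. any target set in a complete graph).
* Component-size ties in `largestConnectedComponent()` resolve to the
  component containing the lexicographically smallest member, making every
  output deterministic.
* One master seed drives everything; each analysis derives per-replicate
  seeds by fixed integer arithmetic (Mersenne-Twister underneath), so
  results are independent of replicate evaluation order and bundles are
  byte-identical across runs with the same seed.
* IDs are canonicalized by uppercasing and whitespace-stripping only; the
  package deliberately does no Entrez↔symbol mapping — inputs must arrive
  in a single namespace.

## Design choices that were genuinely open

* **LCC scope.** For compound-module significance the disease-restricted
  subgraph and the full interactome are both defensible substrates; the
  pipeline supports both (`lccScope = "disease"` or `"full"`). The
  disease-restricted variant asks whether a compound's targets cluster
  *within* the disease's own protein neighborhood; the full-graph variant
  asks whether they cluster at all. With small synthetic disease modules
  the restricted variant is mostly degenerate (few compounds map two or
  more targets into a 30-protein subgraph), so the synthetic benchmark
  uses the full scope.
* **Ranking key.** Compounds are ranked by $z_c$, not raw distance: raw
  closest distance confounds target-set degree, which is precisely what
  the null removes. Both signed $z$ and $|z|$ for the shortest metric are
  reported, since either orientation is found in screening tables.
* **Jaccard summary.** The mean is taken over distinct pairs only (strict
  upper triangle); including unit self-similarities would dominate the
  small means typical of compound panels.
* **Negatives in validation.** Compound--disease pairs without a
  therapeutic annotation count as negatives; no per-compound negative cap
  is applied by default.

## What the synthetic generator emulates — and what it does not

`syntheticScenario()` defaults describe the study shape the pipeline
targets: a 2000-node preferential-attachment interactome (attachment 2;
connected by construction, heavy-tailed degrees), a connected 30-protein
disease module grown by seeded BFS, 30 compounds with 10 targets each — 3
signal compounds drawing 70% of their targets from the module and its
first neighbors, 27 null compounds — and a 1000-gene expression matrix
with 26 samples per group, 10% of genes shifted by |log2 FC| = 2 with
Gaussian noise of SD 0.5 (baseline means uniform on [6, 12], a log2
microarray-intensity scale).

Two generator internals deserve explicit statement. First, the
module-overlap targets of a signal compound are drawn stratified — half
from inside the module, half from the adjacent shell. A uniform draw over
module ∪ neighbors lands mostly on the (larger) neighbor shell and
produces planted compounds that are barely closer than chance; the
stratified draw makes the planted signal an actual signal, which is the
generator's contract. Second, null compounds are degree-matched,
bin-by-bin resamples of a signal compound's target profile, so that the
screen's discrimination measures network location and never degree.

Passing benchmarks on these data show that the chain recovers planted
structure at realistic sizes and noise levels. They do not show that any
particular real interactome is complete or unbiased (literature-curated
edges oversample studied proteins), that real compound target lists are
accurate, or that a real disease's proteins form a single coherent module
— all of which are properties of the inputs, not of the method.

## Problem sizes used by the test suite

Unit tests run on toy graphs small enough to enumerate (6--10 nodes, where
every degree-matched replacement set can be listed exhaustively) and on
random graphs of up to 50 nodes checked against Floyd--Warshall and
flood-fill oracles. The end-to-end benchmarks screen the default
2000-node scenario over 50 seeds (proximity, 1000 null replicates per
compound), validate ROC recovery over 20 seeds, and check DEG recovery
over 20 seeds; these sizes give the acceptance checks stable pass/fail
behavior while keeping a full run of the suite in the tens of minutes on
one CPU.

## Known limitations

* Distances are unweighted hops; confidence-weighted or directed
  interactions are out of scope.
* The only null model is node resampling within degree bins; edge-rewiring
  (configuration-model) nulls are not implemented.
* No expression normalization, batch correction or probe collapsing: the
  expression matrix is taken as given on a log2 scale.
* The AUC comparison is a bootstrap, not the DeLong analytic test; for
  very small score sets its p-values are granular
  ($\ge 1/(n_{boot}+1)$).
* Cross-namespace ID mapping is the caller's responsibility.
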