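# netRepurpose

Network-medicine screening of compounds for drug-repurposing potential on a
protein–protein interactome.

Multi-compound preparations (natural products in particular) act through
many protein targets at once, and asking which constituent compound is a
plausible candidate for a disease is naturally a network question: do the
compound's targets sit in the disease's interactome neighborhood?
`netRepurpose` implements that screen for computational biologists as a
tested, seed-reproducible R package:

* **Interactome assembly** — merge/deduplicate edge lists into one
  undirected graph with canonical IDs and a load report.
* **Target-set similarity** — pairwise Jaccard indices
  J(A,B) = |A∩B| / |A∪B| between compound target sets.
* **Disease-module significance** — size of the largest connected component
  (LCC) induced by a compound's targets, z-scored against degree-matched
  random node sets (screen: |z| > 1.70).
* **Network proximity** — closest distance
  d\_c(S,T) = (1/|T|) Σ\_{t∈T} min\_{s∈S} d(s,t) and mean shortest distance
  between compound targets S and disease proteins T, z-scored against the
  same degree-binned null (1000 replicates by default); compounds ranked by
  z\_c and screened to the top k.
* **ROC validation** — proximity scores (−z\_c) against known
  therapeutic/non-therapeutic compound–disease pairs, with a stratified
  bootstrap AUC comparison.
* **Expression follow-up** — Welch + Benjamini–Hochberg differential
  expression (strict |logFC| > 0.5, adjusted p < 0.05), DEG × target
  intersection, degree-ranked hub targets, and per-gene diagnostic ROC with
  Youden cutoffs (AUC > 0.9 = high-accuracy biomarker).
* **Synthetic-data generator** — a scale-free interactome with a planted
  disease module, signal/null compounds, expression with planted effects
  and an association benchmark, so the whole chain runs and is testable
  with no external downloads.

See `vignettes/network-proximity-screening.Rmd` for the methods and design
rationale.

## Worked example

Screen a synthetic study — a 2000-node scale-free interactome with a
30-protein disease module, 3 planted signal compounds and 27 degree-matched
null compounds:

```r
library(netRepurpose)

sc <- syntheticScenario(seed = 7)
st <- simulateStudy(sc)
st$interactome
#> Interactome with 2000 proteins and 3997 interactions
#>   load: 3997 records, 0 self-loops dropped, 0 duplicates collapsed

# proximity of each compound's targets to the disease module
res <- lapply(st$compounds$sets, function(s)
  networkProximity(st$interactome, s, st$module, st$bins,
                   nReps = 1000, seed = 7))
head(proximityTable(res)[, 1:7], 6)
#>       compound d_closest z_closest d_shortest z_shortest
#> 1  CMPD_SIG_01      1.77   -2.8443       3.33    -4.6273
#> 2  CMPD_SIG_02      1.67   -2.6988       3.15    -5.3040
#> 3  CMPD_SIG_03      1.73   -3.2816       3.49    -3.7355
#> 4 CMPD_NULL_01      2.83   -0.0213       4.01    -0.8288
#> 5 CMPD_NULL_02      2.83    0.3291       4.05     0.0558
#> 6 CMPD_NULL_03      2.43   -1.2850       3.91    -1.3494
```

The planted compounds are two to three hops closer than degree-matched
chance (z\_closest ≈ −2.7 to −3.3); null compounds hover around z ≈ 0.
The planted module itself is far more interconnected than chance:

```r
lccZScore(st$interactome, st$module, st$bins, nReps = 1000, seed = 7)
#> LCCResult 'DISEASE_MODULE': lcc = 30/30 targets, z = 24.27, significant = TRUE
```

and proximity separates the planted therapeutic associations perfectly on
this seed:

```r
scored <- scorePairs(st$interactome,
                     st$compounds$sets[st$compounds$truth$is_signal],
                     st$associations$diseaseSets,
                     pairs = st$associations$pairs,
                     bins = st$bins, nReps = 1000, seed = 7)
rocAuc(scored$score, scored$label)
#> ROCResult: AUC = 1 (30 positives, 30 negatives)
```

The same operations run on real inputs: an edge-list TSV
(`readEdgeList()`), compound target sets in GMT or TSV
(`readTargetSets()`), a disease protein list (`readNodeSet()`), an
association table (`readAssociations()`) and an expression matrix with a
sample sheet (`readExpressionTSV()`). `runPipeline(runConfig(...))`
orchestrates all ten stages and writes per-stage TSV/JSON plus a manifest;
`inst/scripts/netrepurpose.R` is a thin shell dispatcher over the same
functions.

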