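Package: netRepurpose
Title: Network Medicine Proximity Screening for Drug Repurposing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Network-medicine screens for compounds with drug-repurposing
    potential on a protein-protein interactome: significance of the largest
    connected component (LCC) formed by a compound's targets against a
    degree-preserving null, closest/shortest network proximity z-scores
    between compound targets and disease proteins, target-set Jaccard
    similarity, ROC validation of proximity against known indications,
    differential-expression/target intersection, degree-ranked hub targets
    and per-gene diagnostic ROC cutoffs, plus a synthetic-data generator
    with planted signal so the whole chain can be benchmarked end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    fgsea,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GraphAndNetwork, NetworkInference, SystemsBiology,
    DifferentialExpression, Classification
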