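Package: pcmbench
Title: Leakage-Controlled Benchmarks for Proteochemometric Drug-Target
    Interaction Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing and evaluating machine-learning
    benchmarks for drug-target interaction (DTI) prediction. Implements
    similarity-network-based train/test splitting (random,
    dissimilar-compound, and fully-dissimilar splits via Louvain community
    pruning of a heterogeneous protein/compound bioactivity network),
    bioactivity dataset filtering rules for censored and uninformative
    measurements, protein sequence descriptors (dipeptide deviation from
    expected mean, total amino acid properties, subsequence profile maps,
    random baselines), ECFP4 compound fingerprints with Tanimoto
    similarity, a proteochemometric random-forest modelling harness with
    nested cross-validation, corrected performance metrics
    (median-corrected RMSE and MCC, six-bin multiclass MCC), and
    diagnostics for applicability domain, covariate shift, and model
    prediction agreement. A synthetic-data generator with controlled
    compound-family and protein-cluster similarity structure makes every
    component testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    randomForest,
    e1071,
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
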