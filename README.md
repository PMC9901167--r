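# pcmbench

Leakage-controlled benchmark construction and evaluation for
machine-learning drug–target interaction (DTI) prediction.

## The problem

Proteochemometric (PCM) models predict the bioactivity of a
(compound, protein) pair from the concatenation of a compound
fingerprint and a protein sequence descriptor. Reported performance of
such models depends dramatically on how bioactivity records are split
into training and test folds: under a random split, near-identical
compounds and homologous proteins appear on both sides, and a model can
score highly by memorizing similarity rather than by learning anything
about interactions. `pcmbench` provides the machinery to build and
diagnose splits that control this leakage, plus the corrected metrics
needed to evaluate regression-based DTI models honestly:

- **Random split** — records assigned uniformly; the easy (and
  over-optimistic) baseline setting.
- **Dissimilar-compound split** — connected components of the
  compound-similarity graph (Tanimoto ≥ 0.5 on ECFP4 fingerprints,
  `T(A,B) = |A∩B| / |A∪B|`) are assigned whole to one fold, so no
  similar compound pair crosses folds.
- **Fully-dissimilar split** — a heterogeneous network is built with
  compound and protein nodes and three edge types (compound–compound
  similarity, protein–protein similarity from UniRef50-style cluster
  membership, and bioactivity edges). Whole connected components go to
  one fold; while the target test fraction is unreachable, the giant
  component is subdivided by Louvain community detection and
  cross-community bioactivity edges (or crossing compound nodes) are
  discarded. Afterwards neither similar compounds nor same-cluster
  proteins cross folds.

Around the splitters the package implements: dataset filters for
censored (assay-floor) activities and for compounds/targets whose
bioactivity profiles are predictable by memorization; compound-centric
classification dataset construction with similarity-constrained
negative augmentation; native protein descriptors (dde, taap, spmap,
random baselines) and ECFP4 fingerprints; a PCM random-forest harness
(100 trees, one third of features per split) and nested cross-validated
classification (10-fold inner, 5-fold outer); and diagnostics
(k-NN applicability domain, KS / chi-square covariate-shift tests,
pairwise-similarity histograms, prediction-agreement matrices with
clustered heatmap ordering, and 2-D embeddings).

Evaluation metrics include RMSE, Spearman's ρ, MCC

```
MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))
```

and two corrected variants for regression output: **median-corrected**
RMSE/MCC (predictions shifted so their median equals the truth median,
removing systematic offset before scoring) and a **six-bin multiclass
MCC** (pChEMBL classes <5, [5,5.5), [5.5,6), [6,6.5), [6.5,7), ≥7;
macro-averaged one-vs-rest MCC).

A synthetic-data generator creates compound families with controlled
Tanimoto structure, protein clusters with controlled sequence
divergence, and bioactivities with family/cluster/interaction effects
and censoring at pChEMBL = 5, so every component is testable without
downloads.

## Worked example

```r
library(pcmbench)

cfg <- synthetic_config(n_compound_families = 12, compounds_per_family = 6,
                        n_protein_clusters = 8, proteins_per_cluster = 4,
                        fingerprint_bits = 256, screen_block_prob = 0.5,
                        density = 0.4, seed = 42)
bench <- gen_benchmark(cfg)
bench$table
#> <bioactivity_table> 366 records, 70 compounds, 32 proteins
#>   record_id compound_id protein_id activity
#> 1         1   cmp005_01  prot01_01 6.175752
#> 2         2   cmp005_02  prot01_01 6.735754
#> ...

cc <- compound_similarity_edges(bench$compounds$fingerprints)
cc <- cc[cc$from %in% bench$table$compound_id &
         cc$to %in% bench$table$compound_id, ]
pp <- protein_similarity_edges(bench$proteins$clusters)
pp <- pp[pp$from %in% bench$table$protein_id &
         pp$to %in% bench$table$protein_id, ]
graph <- build_hetero_graph(bench$table, cc, pp)
graph
#> <hetero_graph> 70 compounds, 32 proteins; edges: 366 bioactivity, 171 CC_SIM, 48 PP_SIM

s_easy <- split_random(bench$table, 0.15, seed = 42)
s_hard <- split_fully_dissimilar(graph, 0.15, seed = 42)
s_hard
#> <split_result> strategy=fully_dissimilar: 147 train / 22 test / 197 discarded (test fraction 0.130 of retained)

prot <- protein_feature_table(bench$proteins$sequences, "taap")
m <- assemble_pcm_matrix(bench$table, prot, bench$compounds$fingerprints, "pcm")
spearman_on <- function(split) {
  tr <- match(split$train, m$record_ids)
  te <- match(split$test, m$record_ids)
  fit <- train_rf_regressor(subset_pair_matrix(m, tr), seed = 42)
  pred <- predict(fit, subset_pair_matrix(m, te))
  spearman_rho(m$y[te], pred)
}
round(c(random = spearman_on(s_easy), fully_dissimilar = spearman_on(s_hard)), 3)
#>           random fully_dissimilar
#>             0.95            -0.37
```

The same model family scores ρ = 0.95 under a random split and
essentially zero (here −0.37 on a 22-record test fold; the average over
seeds is ≈ 0) once no similar compound or same-cluster protein crosses
folds: the random-split number measures similarity leakage, not
interaction learning. `difficulty_benchmark()` runs this comparison
over multiple seeds, and `baseline_benchmark()` adds the
random-feature floor.

A config-driven entry point mirrors this flow from the shell
(`inst/cli/pcmbench.R`): `simulate`, `featurize`, `split`, `filter`,
`train`, `evaluate` and `diagnose` subcommands, each writing a manifest
of its resolved parameters.

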