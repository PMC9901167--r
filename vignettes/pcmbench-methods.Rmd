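---
title: "Leakage-controlled DTI benchmarks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leakage-controlled DTI benchmarks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its methodology: what the
splitting strategies guarantee and how they are computed, what the
synthetic benchmark emulates (and what it deliberately does not), the
corrected metrics, the numerical conventions, and the design decisions
that were genuinely open.

## 1. Why split construction is the central problem

A proteochemometric (PCM) model predicts the bioactivity `y` (pChEMBL
or pKd, i.e. −log10 of a molar activity) of a (compound, protein) pair
from the concatenation of a compound fingerprint and a protein
descriptor vector. Bioactivity corpora are dominated by congeneric
chemical series and homologous target panels, so a uniformly random
train/test split places near-duplicates of most test items in the
training fold. A flexible learner then scores highly by interpolating
between near-duplicates — performance that does not transfer to novel
chemistry or novel targets.

`pcmbench` treats similarity explicitly and binarizes it:

* compounds are *similar* iff Tanimoto(ECFP4) ≥ 0.5;
* proteins are *similar* iff they share a cluster in a supplied
  cluster map (UniRef50-style membership, the binary stand-in for 50%
  sequence identity). When a precomputed identity matrix is available
  instead, `similarity_matrix_edges()` thresholds it.

Three splits of increasing difficulty are provided. `split_random()`
is the leaky baseline. `split_dissimilar_compound()` assigns connected
components of the compound-similarity graph to folds as wholes, so the
defining constraint — no train/test compound pair at Tanimoto ≥ 0.5 —
holds by construction; proteins may still be shared, which matches the
use case of finding novel chemistry for well-studied targets.
`split_fully_dissimilar()` additionally forbids same-cluster protein
pairs across folds, the regime of predicting for novel targets *and*
novel chemistry.

## 2. The network-based fully-dissimilar split

The heterogeneous network (`build_hetero_graph()`) has one node per
compound and protein and three undirected edge types: `CC_SIM`,
`PP_SIM` (cliques within each protein cluster), and one `BIOACTIVITY`
edge per record. Two disconnected components share no similarity,
direct or transitive, so whole components can be assigned to folds
freely.

The algorithm:

1. **Cluster contraction.** Each PP_SIM clique is contracted to a
   super-node before anything else. Community detection therefore
   *cannot* separate same-cluster proteins, and no protein cluster ever
   spans folds. (Discarding rules are only defined for bioactivity and
   compound-similarity edges; contraction removes the protein case by
   construction.)
2. **Feasibility check.** Components are assigned to folds by an exact
   subset-sum search for the set of whole components whose record count
   is closest to the target test size (components visited in a seeded
   shuffle, stably ordered largest-first, which fixes ties
   deterministically). The split is feasible when the achieved test
   fraction is within `tolerance` (default ±0.05) of `test_fraction`
   (default 0.15) and both folds are nonempty.
3. **Louvain pruning.** While infeasible, Louvain communities (seeded;
   `resolution` default 1.0) are detected in the record-largest
   component. Bioactivity edges whose endpoints fall in different
   communities are discarded (their records go to the `discarded`
   fold). A compound-similarity edge crossing communities cannot be
   discarded alone — that would silently leak similarity — so the
   endpoint compound with fewer remaining records is removed together
   with its records (ties broken toward the lexicographically smaller
   id, minimizing data loss deterministically). At most `max_rounds`
   (default 10) pruning rounds are attempted, after which the achieved
   fractions are reported in the error.

Two numerical details matter in practice. If Louvain returns a single
community at the requested resolution, the round would make no
progress; the resolution is then escalated (×1.5, up to 12 attempts)
for that round only. And the subset-sum assignment, rather than a
one-pass greedy, is what allows feasibility directly after the first
pruning round in most cases — every extra round discards more data.

`harmonize_splits()` removes the reference split's discarded records
from companion splits so that all strategies cover an identical record
universe when a matched comparison is wanted.

## 3. The synthetic benchmark: what it emulates

`synthetic_config()` describes a data-generating process with the
similarity and effect structure the splitters and models care about:

* **Compound families.** Each family has a template fingerprint (bits
  set with probability `template_density` = 0.1); members flip each bit
  independently with `bit_flip_prob` = 0.01. Within-family Tanimoto is
  then well above 0.5 and between-family well below, so families are
  exactly the similarity components.
* **Protein clusters.** Each cluster has a random ancestor sequence;
  members substitute residues i.i.d. at `mutation_rate` = 0.05. The
  cluster map is the ground-truth similarity relation.
* **Activities.** `y = base + family effect + cluster effect +
  (family × cluster) interaction + N(0, noise_sd)`, effects drawn once
  per level from centered Gaussians. `activity_base` = 6.5 sits in the
  middle of the 5.7–7.1 range of median pChEMBL values typical of
  curated family datasets. Values below `censor_floor` = 5 are recorded
  exactly at 5, reproducing the assay-floor artifact of Kd panels
  (no response at the 10 µM maximum dose recorded as pKd = 5).
* **Screening structure.** With `screen_block_prob` = 1 (the default) a
  uniform random fraction `density` of all pairs is measured. Real
  bioactivity matrices are not uniform: compound series are screened
  against panels of related targets, making the bioactivity network
  modular. Setting `screen_block_prob` < 1 first samples whole
  (family × cluster) panels, then pairs within them at `density`. A
  uniform network is nearly unmodular, so community pruning must
  discard most records to disconnect it; panel screening reproduces
  the modular regime in which the network split is economical.

What the generator does *not* emulate: real chemistry (fingerprints
are abstract bit vectors, not hashed molecular neighborhoods),
realistic sequence evolution (i.i.d. substitutions only), assay noise
heterogeneity, and any transferable structure–activity relationship
that would let a model generalize across families. Consequently a
fully-dissimilar split on synthetic data has a true skill *floor* of
zero — useful for testing that nothing leaks, but not evidence about
how far real descriptors generalize on real data.

## 4. The packaged difficulty benchmark

`benchmark_config()` freezes the study conditions used by
`difficulty_benchmark()` and `baseline_benchmark()`: 48 families × 4
compounds, 24 clusters × 3 proteins, 256-bit fingerprints,
`screen_block_prob` = 0.45, `density` = 0.3, `noise_sd` = 0.4
(≈ 1850 records; the fully-dissimilar split retains ≈ 550 and tests on
≈ 85). Many small families/clusters were chosen over few large ones
because the variance of a held-out Spearman on a dissimilarity split is
governed by the number of distinct (family, cluster) blocks in the test
fold, not by its record count; 256-bit fingerprints keep the forests
fast without affecting family separability. Models use taap protein
descriptors plus the generated fingerprints, and the PCM forest
settings (100 trees, a third of the features per split). The ordering
comparison is averaged over 8 seeds and the random-feature baseline
over 12: per-seed Spearman has a standard deviation near 0.16 at this
test-fold size, so these replicate counts put the standard error of the
means near 0.05; replication sharpens the estimate but cannot bias it.
The three strategies are compared unharmonized (each applied to the
full table): harmonizing against the fully-dissimilar reference at desk
scale would shrink every fold to its retained ≈30% and can empty a
companion test fold entirely.

Typical results (seed set 1–8): random ≈ 0.86, dissimilar-compound
≈ 0.37, fully-dissimilar ≈ 0.0, baseline ≈ 0.0 — the monotone
degradation that motivates leakage-controlled evaluation, with a
random-vs-fully-dissimilar gap far above 0.2.

## 5. Filters

`filter_censored()` removes records whose activity equals the assay
floor (tolerance 1e−9). `filter_uninformative()` removes every
compound and target that (a) lies entirely on one side of the activity
threshold, (b) has an active:inactive ratio above 4 or below 1/4, or
(c) varies with standard deviation < 0.3. The threshold `"median"`
resolves against the input table (the conventional 6.2 for the
filtered Davis kinase set); it is resolved *once*, before any removal.
Removal attribution is to the first firing rule (a → b → c). The
marking pass is simultaneous across entities, but removing one entity's
records can leave another entity one-sided, so a single pass is not a
projection; the pass is therefore repeated to a fixed point, which
makes the filter idempotent and removes a superset of what a one-pass
evaluation flags. On typical tables the fixed point is reached after
one or two passes.

`build_compound_centric()` collects the cluster of compounds within
Tanimoto ≥ 0.3 of a center compound, pools records per protein,
aggregates conflicting measurements by median, and labels proteins
active strictly above pChEMBL 5 (a value of exactly 5 is inactive).
`augment_negatives()` balances classes by admitting candidate proteins
that are < 50% similar to every positive and < 80% similar to every
negative — including negatives admitted earlier in the same run — in a
seeded order.

## 6. Metrics and conventions

All confusion-based scores return 0 when their denominator is 0.
Binarization is strict: active iff `y > cutoff`. Spearman uses average
ranks (tie-safe; identical to the classical `1 − 6ΣD²/(n(n²−1))` form
on tie-free data) and refuses constant vectors. Median correction
shifts predictions by `median(y) − median(ŷ)`; it zeroes the median
residual and leaves ranks untouched, but does not necessarily reduce
RMSE. The six activity bins are lower-inclusive:
(−∞,5), [5,5.5), [5.5,6), [6,6.5), [6.5,7), [7,∞); the multiclass MCC
is the unweighted mean of the six one-vs-rest MCCs (a `method = "rk"`
alternative computes the single multi-category correlation instead).
Duplicate (compound, protein) measurements are aggregated by median at
load time, consistent with the median-centric conventions elsewhere.

## 7. Featurization

dde uses the standard genetic code's sense-codon counts (61 codons;
A4 R6 N2 D2 C2 Q2 E2 G4 H2 I3 L6 K2 M1 F2 P4 S6 T4 W1 Y2 V4):
`DDE_i = (Dc_i − Tm_i)/√Tv_i` with `Tm = (Ca/61)(Cb/61)` and
`Tv = Tm(1 − Tm)/(N−1)`. taap sums ten AAindex scales per sequence;
the accessions (documented at `TAAP_PROPERTIES`) are the package's
choice for the ten named properties, frozen by golden tests. spmap
clusters all 5-mers by greedy leader clustering under ungapped BLOSUM62
scores — deterministic (frequency order, lexicographic ties) and
O(k-mers × centers); the center count is dataset-dependent via
`score_threshold`/`max_centers`, not a constant. ECFP4 fingerprints
come from Open Babel (radius 2), OR-folded from its native 4096 bits to
the requested width; hashed bit assignments are toolkit-specific, and
every similarity threshold operates on Tanimoto values, which are
stable under any consistent mapping. Random baselines: `random200`
(Uniform(0,1)^200 per protein) and `random_fingerprint`
(Bernoulli(0.1) bits, matching the sparsity of real ECFP4 vectors).
Descriptors that require external profile databases (PSSM, Pfam,
learned embeddings) are consumed as precomputed vector tables via
`read_vector_table()`.

## 8. Diagnostics

`knn_ad()` scores each test item by the mean similarity of its 5
nearest training items; `ks_shift()` (continuous features, asymptotic
two-sample p-values, α = 0.01) and `chi2_shift()` (binary features, no
continuity correction, α = 0.001 because the chi-square test is
sample-size sensitive; bits constant in both folds are skipped) test
the i.i.d. assumption per dimension. `agreement_matrix()` computes
pairwise percent agreement of model predictions in the six activity
bins and orders models by average-linkage clustering on
(100 − agreement). `embed_2d()` provides a 2-D embedding for visual
fold/group inspection via classical multidimensional scaling of
Euclidean distances — deterministic, with a seeded infinitesimal
jitter only to break exact-duplicate ties.

## 9. Known limitations

* The fully-dissimilar split's data loss depends strongly on the
  modularity of the bioactivity network; on dense unmodular networks
  (uniform screening) most records are discarded to achieve
  disconnection.
* The leakage guarantees are exactly as strong as the binarized
  similarity relations: a cluster map at 50% identity does not exclude
  remote homology, and Tanimoto < 0.5 does not exclude shared
  scaffolds.
* Synthetic benchmarks bound what passing tests show about real data:
  they validate the construction (no leakage, correct ordering, null
  baselines), not the real-data performance of any descriptor.
* `nested_cv_classify()` stratifies outer folds; class balance is
  assumed to be meaningful (as in engineered compound-centric sets).
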