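# Desk-scale split-difficulty benchmark: generates a synthetic
# bioactivity dataset, applies the three splitting strategies, trains a
# PCM random forest per split, and reports held-out Spearman
# correlations, optionally alongside the random-feature baseline model.

#' Default configuration of the split-difficulty benchmark
#'
#' A desk-scale synthetic dataset sized so that the fully-dissimilar
#' split retains a usable test fold: many small compound families and
#' protein clusters, panel-structured screening (as in target-based
#' assay campaigns), and family/cluster/interaction activity effects
#' with censoring at pKd = 5.
#'
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
benchmark_config <- function(seed = 1L) {
  synthetic_config(
    n_compound_families = 48L, compounds_per_family = 4L,
    fingerprint_bits = 256L,
    n_protein_clusters = 24L, proteins_per_cluster = 3L,
    noise_sd = 0.4,
    density = 0.3, screen_block_prob = 0.45,
    seed = seed)
}

# train on s$train, evaluate Spearman on s$test
eval_split_spearman <- function(split, m, seed) {
  tr <- match(split$train, m$record_ids)
  te <- match(split$test, m$record_ids)
  fit <- train_rf_regressor(subset_pair_matrix(m, tr), seed = seed)
  pred <- predict(fit, subset_pair_matrix(m, te))
  spearman_rho(m$y[te], pred)
}

#' Run the split-difficulty benchmark
#'
#' For each seed: generate a synthetic benchmark, build the three
#' train/test splits (random, dissimilar-compound, fully-dissimilar),
#' train a PCM random forest (taap protein descriptors + the generated
#' compound fingerprints) per split, and record the held-out Spearman
#' correlation. Optionally also trains the random-protein +
#' random-compound baseline on the fully-dissimilar split, whose
#' Spearman should hover around zero: with no informative features and
#' no similar entities crossing folds there is nothing to learn.
#'
#' @param seeds integer vector of benchmark seeds.
#' @param config_fn function seed -> [synthetic_config()]
#'   (default [benchmark_config()]).
#' @param test_fraction target test fraction (default 0.15).
#' @param include_baseline also run the random-feature baseline
#'   (default TRUE).
#' @return data frame with one row per seed and columns `random`,
#'   `dissimilar_compound`, `fully_dissimilar`, `baseline` (if
#'   requested), `n_records`, `n_retained`, `n_test`.
#' @export
difficulty_benchmark <- function(seeds = 1:8, config_fn = benchmark_config,
                                 test_fraction = 0.15,
                                 include_baseline = TRUE) {
  force(config_fn)
  rows <- lapply(seeds, function(seed) {
    bench <- gen_benchmark(config_fn(seed))
    tab <- bench$table
    fp <- bench$compounds$fingerprints
    cc <- compound_similarity_edges(fp)
    cc <- cc[cc$from %in% tab$compound_id & cc$to %in% tab$compound_id, ,
             drop = FALSE]
    pp <- protein_similarity_edges(bench$proteins$clusters)
    pp <- pp[pp$from %in% tab$protein_id & pp$to %in% tab$protein_id, ,
             drop = FALSE]
    graph <- build_hetero_graph(tab, cc, pp)
    s_full <- split_fully_dissimilar(graph, test_fraction, seed = seed)
    s_rand <- split_random(tab, test_fraction, seed = seed)
    s_diss <- split_dissimilar_compound(tab, cc, test_fraction, seed = seed)
    prot_ft <- protein_feature_table(bench$proteins$sequences, "taap")
    m <- assemble_pcm_matrix(tab, prot_ft, fp, mode = "pcm")
    out <- data.frame(
      seed = seed,
      random = eval_split_spearman(s_rand, m, seed),
      dissimilar_compound = eval_split_spearman(s_diss, m, seed),
      fully_dissimilar = eval_split_spearman(s_full, m, seed),
      n_records = nrow(tab),
      n_retained = length(s_full$train) + length(s_full$test),
      n_test = length(s_full$test))
    if (include_baseline) {
      rnd_prot <- random200(length(bench$proteins$sequences),
                            seed = seed + 101L)
      rownames(rnd_prot) <- names(bench$proteins$sequences)
      rnd_cmp <- random_fingerprint(nrow(fp), width = ncol(fp),
                                    seed = seed + 211L)
      rownames(rnd_cmp) <- rownames(fp)
      m_rnd <- assemble_pcm_matrix(
        tab, feature_table(rnd_prot, "protein"),
        feature_table(rnd_cmp, "compound"), mode = "pcm")
      out$baseline <- eval_split_spearman(s_full, m_rnd, seed)
    }
    out
  })
  do.call(rbind, rows)
}

#' Run the random-feature baseline on the fully-dissimilar benchmark
#'
#' Lightweight variant of [difficulty_benchmark()] that trains only the
#' random-protein + random-compound baseline model on the
#' fully-dissimilar split of each seeded benchmark. Its held-out
#' Spearman estimates the no-information floor of the benchmark; over
#' many seeds it averages to zero.
#'
#' @inheritParams difficulty_benchmark
#' @return data frame with columns `seed`, `baseline`, `n_test`.
#' @export
baseline_benchmark <- function(seeds = 1:12, config_fn = benchmark_config,
                               test_fraction = 0.15) {
  rows <- lapply(seeds, function(seed) {
    bench <- gen_benchmark(config_fn(seed))
    tab <- bench$table
    fp <- bench$compounds$fingerprints
    cc <- compound_similarity_edges(fp)
    cc <- cc[cc$from %in% tab$compound_id & cc$to %in% tab$compound_id, ,
             drop = FALSE]
    pp <- protein_similarity_edges(bench$proteins$clusters)
    pp <- pp[pp$from %in% tab$protein_id & pp$to %in% tab$protein_id, ,
             drop = FALSE]
    s_full <- split_fully_dissimilar(build_hetero_graph(tab, cc, pp),
                                     test_fraction, seed = seed)
    rnd_prot <- random200(length(bench$proteins$sequences), seed = seed + 101L)
    rownames(rnd_prot) <- names(bench$proteins$sequences)
    rnd_cmp <- random_fingerprint(nrow(fp), width = ncol(fp),
                                  seed = seed + 211L)
    rownames(rnd_cmp) <- rownames(fp)
    m_rnd <- assemble_pcm_matrix(
      tab, feature_table(rnd_prot, "protein"),
      feature_table(rnd_cmp, "compound"), mode = "pcm")
    data.frame(seed = seed,
               baseline = eval_split_spearman(s_full, m_rnd, seed),
               n_test = length(s_full$test))
  })
  do.call(rbind, rows)
}
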