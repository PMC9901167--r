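test_that("generators are deterministic given the config seed", {
  cfg <- synthetic_config(n_compound_families = 3L, compounds_per_family = 4L,
                          n_protein_clusters = 2L, proteins_per_cluster = 3L,
                          seq_length = 40L, seed = 42L)
  a <- gen_benchmark(cfg)
  b <- gen_benchmark(cfg)
  expect_identical(unclass(a$compounds$fingerprints),
                   unclass(b$compounds$fingerprints))
  expect_identical(a$proteins$sequences, b$proteins$sequences)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
})

test_that("degenerate generator settings behave as specified", {
  cfg <- synthetic_config(n_compound_families = 2L, compounds_per_family = 3L,
                          bit_flip_prob = 0, mutation_rate = 0,
                          n_protein_clusters = 3L, proteins_per_cluster = 2L,
                          seq_length = 30L, seed = 1L)
  cmp <- gen_compounds(cfg)
  # zero flip probability: family members identical, Tanimoto 1
  fp <- as.matrix(cmp$fingerprints)
  fam1 <- names(cmp$families)[cmp$families == "fam01"]
  expect_equal(tanimoto(fp[fam1[1], ], fp[fam1[2], ]), 1.0)
  expect_identical(fp[fam1[1], ], fp[fam1[2], ])

  prot <- gen_proteins(cfg)
  expect_length(prot$sequences, 6L)
  expect_length(unique(unclass(prot$clusters)), 3L)
  # zero mutation rate: members identical within cluster
  clu1 <- names(prot$clusters)[unclass(prot$clusters) == "clu01"]
  expect_identical(prot$sequences[[clu1[1]]], prot$sequences[[clu1[2]]])
})

test_that("activities carry the configured effect structure", {
  # all effects and noise zero -> constant at the base
  cfg0 <- synthetic_config(n_compound_families = 2L, compounds_per_family = 2L,
                           n_protein_clusters = 2L, proteins_per_cluster = 2L,
                           seq_length = 20L, family_effect_sd = 0,
                           cluster_effect_sd = 0, interaction_sd = 0,
                           noise_sd = 0, density = 1, censor_floor = NULL,
                           seed = 3L)
  tab0 <- gen_bioactivities(gen_compounds(cfg0), gen_proteins(cfg0), cfg0)
  expect_true(all(tab0$activity == cfg0$activity_base))

  # censoring floors the recorded values exactly
  cfgc <- synthetic_config(n_compound_families = 2L, compounds_per_family = 4L,
                           n_protein_clusters = 2L, proteins_per_cluster = 4L,
                           seq_length = 20L, activity_base = 5.2,
                           family_effect_sd = 1.5, noise_sd = 0.5,
                           density = 1, censor_floor = 5.0, seed = 8L)
  tabc <- gen_bioactivities(gen_compounds(cfgc), gen_proteins(cfgc), cfgc)
  expect_equal(min(tabc$activity), 5.0)
  expect_gt(sum(tabc$activity == 5.0), 0)

  # noise-only config: within-cell sample sd close to noise_sd
  cfgn <- synthetic_config(n_compound_families = 1L,
                           compounds_per_family = 20L,
                           n_protein_clusters = 1L, proteins_per_cluster = 10L,
                           seq_length = 20L, family_effect_sd = 0,
                           cluster_effect_sd = 0, interaction_sd = 0,
                           noise_sd = 0.5, density = 1, censor_floor = NULL,
                           seed = 5L)
  tabn <- gen_bioactivities(gen_compounds(cfgn), gen_proteins(cfgn), cfgn)
  n <- nrow(tabn)
  se_sd <- 0.5 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(tabn$activity) - 0.5), 3 * se_sd)
})

test_that("within-family Tanimoto separates from between-family", {
  cfg <- synthetic_config(n_compound_families = 10L,
                          compounds_per_family = 10L,
                          template_density = 0.1, bit_flip_prob = 0.01,
                          fingerprint_bits = 1024L, seed = 13L)
  cmp <- gen_compounds(cfg)
  fp <- as.matrix(cmp$fingerprints)
  sim <- pcmbench:::tanimoto_matrix(fp)
  same <- outer(cmp$families, cmp$families, "==")
  ut <- upper.tri(sim)
  within <- mean(sim[ut & same])
  between <- mean(sim[ut & !same])
  expect_gt(within, between)
  expect_gt(within - between, 0.3)
})

test_that("a two-way means model recovers the generative effects", {
  cfg <- synthetic_config(n_compound_families = 6L, compounds_per_family = 6L,
                          n_protein_clusters = 5L, proteins_per_cluster = 4L,
                          seq_length = 20L, interaction_sd = 0,
                          noise_sd = 0.3, density = 1, censor_floor = NULL,
                          seed = 17L)
  cmp <- gen_compounds(cfg)
  prot <- gen_proteins(cfg)
  tab <- gen_bioactivities(cmp, prot, cfg)
  eff <- attr(tab, "effects")
  fam <- factor(cmp$families[tab$compound_id])
  clu <- factor(unclass(prot$clusters)[tab$protein_id])
  fit <- lm(tab$activity ~ fam + clu, contrasts = list(fam = "contr.sum",
                                                       clu = "contr.sum"))
  co <- coef(fit)
  fam_hat <- co[grep("^fam", names(co))]
  fam_hat <- c(fam_hat, -sum(fam_hat))
  fam_true <- eff$family - mean(eff$family)
  expect_lt(sqrt(mean((fam_hat - fam_true)^2)), cfg$noise_sd)
  clu_hat <- co[grep("^clu", names(co))]
  clu_hat <- c(clu_hat, -sum(clu_hat))
  clu_true <- eff$cluster - mean(eff$cluster)
  expect_lt(sqrt(mean((clu_hat - clu_true)^2)), cfg$noise_sd)
})

test_that("panel screening restricts measurements to screened blocks", {
  cfg <- synthetic_config(n_compound_families = 8L, compounds_per_family = 4L,
                          n_protein_clusters = 6L, proteins_per_cluster = 3L,
                          seq_length = 20L, density = 1,
                          screen_block_prob = 0.4, seed = 23L)
  cmp <- gen_compounds(cfg)
  prot <- gen_proteins(cfg)
  tab <- gen_bioactivities(cmp, prot, cfg)
  blocks <- unique(paste(cmp$families[tab$compound_id],
                         unclass(prot$clusters)[tab$protein_id]))
  # with density 1, a screened block is fully measured: records are a
  # multiple of the block size, and unscreened blocks contribute nothing
  expect_equal(nrow(tab), length(blocks) * 12L)
  expect_lt(length(blocks), 8L * 6L)
})

test_that("config validation rejects out-of-range values", {
  expect_error(synthetic_config(density = 1.2), "probability")
  expect_error(synthetic_config(noise_sd = -1), "non-negative")
  expect_error(synthetic_config(n_compound_families = 0), "positive integer")
})
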