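test_that("random splits have the requested sizes and are seeded", {
  tab <- bioactivity_table(paste0("c", 1:10), rep("p1", 10), runif(10, 5, 8))
  s <- split_random(tab, 0.3, seed = 4)
  expect_length(s$test, 3L)
  expect_length(s$train, 7L)
  expect_length(s$discarded, 0L)
  expect_identical(split_random(tab, 0.3, seed = 4), s)
  expect_false(identical(split_random(tab, 0.3, seed = 5)$test, s$test))
  # feasibility guard: at least one training record
  s99 <- split_random(tab, 0.999, seed = 1)
  expect_gte(length(s99$train), 1L)
  expect_error(split_random(tab[1, ], 0.5), "at least 2")
})

test_that("component assignment picks the subset closest to the target", {
  # components of 2 and 1 records at fraction 1/3: the singleton is test
  tab <- bioactivity_table(c("c1", "c2", "c3"), paste0("p", 1:3),
                           c(6, 7, 8))
  cc <- data.frame(from = "c1", to = "c2", similarity = 0.9)
  s <- split_dissimilar_compound(tab, cc, 1 / 3, seed = 1)
  expect_equal(s$test, tab$record_id[tab$compound_id == "c3"])
  expect_length(s$train, 2L)
})

test_that("dissimilar-compound splits never leak similar compounds", {
  cfg <- synthetic_config(n_compound_families = 8L, compounds_per_family = 5L,
                          n_protein_clusters = 4L, proteins_per_cluster = 3L,
                          seq_length = 30L, density = 0.5, seed = 29L)
  bench <- gen_benchmark(cfg)
  tab <- bench$table
  fp <- bench$compounds$fingerprints
  cc <- compound_similarity_edges(fp)
  cc <- cc[cc$from %in% tab$compound_id & cc$to %in% tab$compound_id, ]
  s <- split_dissimilar_compound(tab, cc, 0.2, seed = 7)
  viol <- oracle_leakage(tab, s, fp)
  expect_equal(viol$compound, 0L)
  # partition invariant
  expect_setequal(c(s$train, s$test, s$discarded), tab$record_id)
  # no cc edges at all: record-level split by compound still partitions
  s0 <- split_dissimilar_compound(tab, NULL, 0.2, seed = 7)
  expect_setequal(c(s0$train, s0$test), tab$record_id)

  # a single component covering everything is infeasible
  tab2 <- bioactivity_table(c("c1", "c2"), c("p1", "p2"), c(6, 7))
  cc2 <- data.frame(from = "c1", to = "c2")
  expect_error(split_dissimilar_compound(tab2, cc2, 0.5, seed = 1),
               "single compound component")
})

test_that("the fully-dissimilar toy discards exactly the bridging record", {
  tab <- bioactivity_table(c("c1", "c2", "c1"), c("p1", "p2", "p2"),
                           c(6.0, 7.0, 5.5))
  cm <- cluster_map(c(p1 = "u1", p2 = "u2"))
  g <- build_hetero_graph(tab, NULL, protein_similarity_edges(cm))
  s <- split_fully_dissimilar(g, 0.5, seed = 1)
  bridge <- tab$record_id[tab$compound_id == "c1" & tab$protein_id == "p2"]
  expect_equal(s$discarded, bridge)
  expect_length(s$train, 1L)
  expect_length(s$test, 1L)
  expect_setequal(c(s$train, s$test), setdiff(tab$record_id, bridge))
})

test_that("already disconnected graphs split without discarding", {
  tab <- bioactivity_table(c("c1", "c2", "c3", "c4"),
                           c("p1", "p1", "p2", "p2"),
                           c(6, 6.5, 7, 7.5))
  g <- build_hetero_graph(tab)
  s <- split_fully_dissimilar(g, 0.5, seed = 2)
  expect_length(s$discarded, 0L)
  expect_length(s$test, 2L)
})

test_that("fully-dissimilar splits satisfy both leakage constraints", {
  bench <- gen_benchmark(benchmark_config(seed = 31L))
  tab <- bench$table
  fp <- bench$compounds$fingerprints
  cc <- compound_similarity_edges(fp)
  cc <- cc[cc$from %in% tab$compound_id & cc$to %in% tab$compound_id, ]
  pp <- protein_similarity_edges(bench$proteins$clusters)
  pp <- pp[pp$from %in% tab$protein_id & pp$to %in% tab$protein_id, ]
  g <- build_hetero_graph(tab, cc, pp)
  s <- split_fully_dissimilar(g, 0.15, seed = 31)
  viol <- oracle_leakage(tab, s, fp, bench$proteins$clusters)
  expect_equal(viol$compound, 0L)
  expect_equal(viol$protein, 0L)
  expect_setequal(c(s$train, s$test, s$discarded), tab$record_id)
  achieved <- length(s$test) / (length(s$train) + length(s$test))
  expect_lt(abs(achieved - 0.15), 0.05 + 1e-9)
  # determinism incl. the seeded Louvain stage
  expect_identical(split_fully_dissimilar(g, 0.15, seed = 31), s)
})

test_that("infeasible fully-dissimilar splits report achievable fractions", {
  tab <- bioactivity_table(c("c1", "c1"), c("p1", "p2"), c(6, 7))
  cm <- cluster_map(c(p1 = "u1", p2 = "u1"))
  g <- build_hetero_graph(tab, NULL, protein_similarity_edges(cm))
  expect_error(split_fully_dissimilar(g, 0.5, max_rounds = 2, seed = 1),
               "infeasible")
})

test_that("harmonization moves reference discards into every split", {
  tab <- bioactivity_table(paste0("c", 1:8), rep(c("p1", "p2"), 4),
                           runif(8, 5, 8))
  ref <- structure(list(train = c(1L, 2L, 3L), test = c(4L, 5L),
                        discarded = c(6L, 7L, 8L),
                        params = list(strategy = "fully_dissimilar")),
                   class = "split_result")
  other <- split_random(tab, 0.25, seed = 3)
  h <- harmonize_splits(ref, list(other))[[1]]
  expect_true(all(c(6L, 7L, 8L) %in% h$discarded))
  expect_false(any(c(6L, 7L, 8L) %in% c(h$train, h$test)))
  expect_setequal(c(h$train, h$test, h$discarded), tab$record_id)
  # identical retained universes across harmonized splits
  expect_setequal(c(h$train, h$test), c(ref$train, ref$test))

  # reference without discards leaves others unchanged
  ref0 <- split_random(tab, 0.25, seed = 9)
  h0 <- harmonize_splits(ref0, list(other))[[1]]
  expect_equal(h0$train, other$train)
  expect_equal(h0$test, other$test)

  # mismatched universes are rejected
  tab_small <- tab[1:5, ]
  class(tab_small) <- c("bioactivity_table", "data.frame")
  other_small <- split_random(tab_small, 0.4, seed = 1)
  expect_error(harmonize_splits(ref, list(other_small)), "universe")
})
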