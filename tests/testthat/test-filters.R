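test_that("censored-value removal targets exactly the assay floor", {
  tab <- bioactivity_table(paste0("c", 1:3), rep("p1", 3), c(5.0, 6.1, 5.0))
  res <- filter_censored(tab)
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$table$activity, 6.1)
  expect_length(res$report$removed_censored, 2L)

  clean <- bioactivity_table(paste0("c", 1:3), rep("p1", 3), c(5.3, 6, 7))
  expect_equal(nrow(filter_censored(clean)$table), 3L)

  # parameterized floor
  res7 <- filter_censored(clean, floor = 7.0)
  expect_equal(res7$table$activity, c(5.3, 6))
})

test_that("uninformative-entity rules fire as specified", {
  # rule (a): one-sided target
  tab_a <- bioactivity_table(paste0("c", 1:6),
                             c(rep("pA", 3), rep("pB", 3)),
                             c(7.0, 7.5, 8.0, 5.0, 5.6, 7.1))
  res_a <- filter_uninformative(tab_a, threshold = 6.2, min_sd = 0)
  expect_true("pA" %in% res_a$report$removed_by_rule$a$entities)
  expect_false("pB" %in% unlist(lapply(res_a$report$removed_by_rule,
                                       `[[`, "entities")))

  # rule (b): 5 actives to 1 inactive exceeds the ratio cap of 4
  tab_b <- bioactivity_table(paste0("c", 1:6), rep("pA", 6),
                             c(7, 7.4, 8, 8.5, 9, 5.0))
  res_b <- filter_uninformative(tab_b, threshold = 6.2, min_sd = 0)
  expect_true("pA" %in% res_b$report$removed_by_rule$b$entities)

  # rule (c): narrow spread below min_sd
  tab_c <- bioactivity_table(paste0("c", 1:4),
                             c(rep("pA", 3), "pB"),
                             c(6.0, 6.1, 6.05, 4.0))
  expect_lt(sd(c(6.0, 6.1, 6.05)), 0.3)
  res_c <- filter_uninformative(tab_c, threshold = 6.02, ratio_cap = 100)
  expect_true("pA" %in% res_c$report$removed_by_rule$c$entities)
})

test_that("the median threshold resolves from the input table", {
  tab <- bioactivity_table(paste0("c", 1:5), rep(c("p1", "p2"), c(3, 2)),
                           c(5, 6, 7, 8, 9))
  res <- filter_uninformative(tab, threshold = "median")
  expect_equal(res$report$threshold_used, 7)
  expect_error(filter_uninformative(tab[0, ]), "empty")
})

test_that("filtering equals an independent per-entity oracle and is idempotent", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(30:120, 1)
    tab <- bioactivity_table(
      sample(paste0("c", 1:12), n, replace = TRUE),
      sample(paste0("p", 1:8), n, replace = TRUE),
      round(runif(n, 4, 9), 2))
    thr <- 6.2
    res <- filter_uninformative(tab, threshold = thr)
    # oracle: naive iterated per-entity re-evaluation
    expect_setequal(res$table$record_id, oracle_uninformative(tab, thr))
    # the filter removes a superset of the one-pass evaluation
    one_pass <- oracle_uninformative(tab, thr, iterate = FALSE)
    expect_true(all(res$table$record_id %in% one_pass))
    # idempotence at a fixed threshold (empty tables are an input error
    # by contract, so only nonempty survivors are refiltered)
    if (nrow(res$table) > 0) {
      res2 <- filter_uninformative(res$table, threshold = thr)
      expect_equal(as.data.frame(res2$table), as.data.frame(res$table))
    }
  }
  # censored filter is idempotent too
  tab <- bioactivity_table(paste0("c", 1:4), rep("p", 4), c(5, 5, 6, 7))
  once <- filter_censored(tab)$table
  expect_equal(as.data.frame(filter_censored(once)$table),
               as.data.frame(once))
})

test_that("compound-centric datasets pool members and label by median", {
  fp <- rbind(center = c(1, 1, 1, 1, 0, 0, 0, 0),
              near = c(1, 1, 1, 0, 0, 0, 0, 0),    # tanimoto 0.75
              far = c(0, 0, 0, 0, 1, 1, 1, 1))     # tanimoto 0
  tab <- bioactivity_table(
    c("center", "near", "near", "far", "center"),
    c("p1", "p1", "p2", "p3", "p4"),
    c(4.0, 8.0, 6.0, 9.0, 5.0))
  ds <- build_compound_centric("center", fp, tab)
  expect_setequal(ds$member_ids, c("center", "near"))
  # p1 pools 4.0 and 8.0 -> median 6.0 -> positive
  expect_true("p1" %in% ds$positives)
  # p4 at exactly 5.0 -> negative (boundary is inactive)
  expect_true("p4" %in% ds$negatives)
  # far compound's proteins are not part of the dataset
  expect_false("p3" %in% c(ds$positives, ds$negatives))
  expect_error(build_compound_centric("nope", fp, tab), "unknown center")

  # center-only dataset with one active record
  tab1 <- bioactivity_table("center", "p1", 6.0)
  ds1 <- build_compound_centric("center", fp, tab1)
  expect_equal(ds1$positives, "p1")
  expect_length(ds1$negatives, 0L)
})

test_that("negative augmentation enforces both similarity caps", {
  ds <- structure(list(center_id = "c", member_ids = "c",
                       positives = c("pos1", "pos2"), negatives = "neg1",
                       protein_activity = NULL),
                  class = "compound_centric_dataset")
  prots <- c("pos1", "pos2", "neg1", "cand1", "cand2", "cand3")
  sim <- matrix(10, length(prots), length(prots),
                dimnames = list(prots, prots))
  diag(sim) <- 100
  sim["cand1", "pos1"] <- sim["pos1", "cand1"] <- 90  # too close to a positive
  out <- augment_negatives(ds, sim, c("cand1", "cand2", "cand3"), seed = 2)
  expect_false("cand1" %in% out$negatives)
  expect_length(out$negatives, 2L)  # balanced with the 2 positives

  # freshly added negatives constrain later candidates
  sim2 <- sim
  sim2["cand2", "cand3"] <- sim2["cand3", "cand2"] <- 90
  out2 <- augment_negatives(ds, sim2, c("cand2", "cand3"), seed = 2)
  expect_length(out2$negatives, 2L)  # only one of the mutually close pair joins
  expect_length(intersect(c("cand2", "cand3"), out2$negatives), 1L)

  # insufficient candidates: best effort with a warning
  expect_warning(
    short <- augment_negatives(ds, sim["cand1", , drop = FALSE], "cand1",
                               seed = 1),
    "balance")
  expect_length(short$negatives, 1L)
})
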