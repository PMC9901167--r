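test_that("knn applicability scores equal a sort-and-average oracle", {
  set.seed(83)
  train <- matrix(rbinom(8 * 32, 1, 0.3), 8,
                  dimnames = list(paste0("tr", 1:8), NULL))
  test <- matrix(rbinom(3 * 32, 1, 0.3), 3,
                 dimnames = list(paste0("te", 1:3), NULL))
  scores <- knn_ad(test, train, k = 5)
  for (i in 1:3) {
    sims <- vapply(1:8, function(j) oracle_tanimoto(test[i, ], train[j, ]),
                   numeric(1))
    expect_equal(unname(scores[i]), mean(sort(sims, decreasing = TRUE)[1:5]))
  }
  # identical test item among >= k identical training items scores 1
  same <- matrix(rep(test[1, ], 6), 6, byrow = TRUE,
                 dimnames = list(paste0("s", 1:6), NULL))
  expect_equal(unname(knn_ad(test[1, , drop = FALSE], same, k = 5)[1]), 1)
  # k larger than the training set: mean over everything
  expect_equal(unname(knn_ad(test, train, k = 50)),
               unname(rowMeans(pcmbench:::tanimoto_matrix(test, train))))
  expect_error(knn_ad(test, train[0, , drop = FALSE]), "empty")

  # monotone under training-set shrinkage
  full <- knn_ad(test, train, k = 3)
  sub <- knn_ad(test, train[1:4, ], k = 3)
  expect_true(all(sub <= full + 1e-12))
})

test_that("ad_report summarizes reliable predictions", {
  rep <- ad_report(c(0.9, 0.2, 0.5), y_true = c(6, 7, 8),
                   y_pred = c(6.2, 8.5, 7.9), error_threshold = 1)
  expect_equal(rep$reliable_fraction, 2 / 3)
  expect_equal(rep$abs_error[2], 1.5)
})

test_that("prediction agreement uses the six-bin classes symmetrically", {
  a <- c(4.5, 5.2, 6.1, 7.4)
  expect_equal(prediction_agreement(a, a), 100)
  b <- c(5.1, 5.7, 6.6, 6.9)  # every value in a different bin than a
  expect_equal(prediction_agreement(a, b), 0)
  c_ <- c(4.9, 5.4, 6.05, 8.0)  # same bins as a
  expect_equal(prediction_agreement(a, c_), 100)
  expect_equal(prediction_agreement(a, b), prediction_agreement(b, a))
  expect_error(prediction_agreement(a, b[1:3]), "equal length")
})

test_that("agreement matrices cluster block structure contiguously", {
  base1 <- c(4.5, 5.2, 6.1, 7.4, 6.6)
  base2 <- c(7.2, 6.7, 4.3, 5.1, 5.6)
  preds <- list(a1 = base1, a2 = base1 + 0.05,
                b1 = base2, b2 = base2 + 0.05)
  am <- agreement_matrix(preds)
  M <- am$matrix
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(100, 4))
  expect_true(all(M >= 0 & M <= 100))
  # the two blocks stay contiguous in leaf order
  pos <- match(c("a1", "a2"), am$order)
  expect_equal(abs(diff(pos)), 1L)
  expect_equal(M["a1", "a2"], 100)
  expect_lt(M["a1", "b1"], 50)

  expect_error(agreement_matrix(preds[1]), "two models")
})

test_that("KS shift detection matches the empirical-CDF oracle", {
  set.seed(89)
  x <- rnorm(20)
  y <- rnorm(20, 1)
  r <- ks_shift(matrix(x, 20), matrix(y, 20), alpha = 0.05)
  expect_equal(r$statistic, oracle_ks_distance(x, y), tolerance = 1e-12)

  # identical folds: zero distance everywhere
  A <- matrix(runif(100), 20)
  r0 <- ks_shift(A, A)
  expect_true(all(r0$statistic == 0))
  expect_equal(r0$n_significant, 0L)

  # a 10-sd shift in one of three features is flagged
  set.seed(90)
  tr <- matrix(rnorm(500 * 3), 500)
  te <- matrix(rnorm(500 * 3), 500)
  te[, 2] <- te[, 2] + 10
  rs <- ks_shift(tr, te, alpha = 0.01)
  expect_true(rs$p_value[2] < 0.01)
  expect_equal(rs$n_significant, 1L)
  expect_error(ks_shift(tr, te[, 1:2]), "dimensions differ")
})

test_that("chi-square shift matches the hand formula and skips constants", {
  # printed 2x2 toy: train 30/10, test 10/30 (zeros/ones)
  tr <- matrix(rep(c(0, 1), c(30, 10)), 40)
  te <- matrix(rep(c(0, 1), c(10, 30)), 40)
  r <- chi2_shift(tr, te)
  # chi2 = n (ad - bc)^2 / (row and column margins)
  expect_equal(r$statistic, 80 * (30 * 30 - 10 * 10)^2 / (40 * 40 * 40 * 40))

  # extreme association is significant at alpha 0.001
  tr2 <- matrix(0, 200, 1)
  te2 <- matrix(1, 200, 1)
  r2 <- chi2_shift(tr2, te2)
  expect_equal(r2$n_significant, 1L)

  # bits constant in both folds are skipped
  tr3 <- cbind(rep(1, 50), rbinom(50, 1, 0.5))
  te3 <- cbind(rep(1, 50), rbinom(50, 1, 0.5))
  r3 <- chi2_shift(tr3, te3)
  expect_true(r3$skipped[1])
  expect_false(r3$skipped[2])

  # matched distributions: nothing significant
  set.seed(91)
  A <- matrix(rbinom(200 * 5, 1, 0.3), 200)
  B <- matrix(rbinom(200 * 5, 1, 0.3), 200)
  expect_equal(chi2_shift(A, B)$n_significant, 0L)
})

test_that("shift tests hold the false-positive rate on random splits", {
  set.seed(92)
  dim <- 40
  n_sig <- replicate(10, {
    A <- matrix(rnorm(120 * dim), 120)
    B <- matrix(rnorm(120 * dim), 120)
    ks_shift(A, B, alpha = 0.05)$n_significant
  })
  expected <- 0.05 * dim
  se <- sqrt(10 * dim * 0.05 * 0.95) / 10
  expect_lt(abs(mean(n_sig) - expected), 3 * se + 0.5)
})

test_that("similarity histograms partition pairs and normalize to density", {
  set.seed(93)
  items <- matrix(rbinom(10 * 64, 1, 0.2), 10,
                  dimnames = list(paste0("x", 1:10), NULL))
  groups <- setNames(rep(c("train", "test"), c(6, 4)), rownames(items))
  h <- pairwise_similarity_histogram(items, groups)
  n_pairs <- h$`train-train`$n_pairs + h$`test-test`$n_pairs +
    h$`train-test`$n_pairs
  expect_equal(n_pairs, choose(10, 2))
  expect_equal(h$`train-train`$n_pairs, choose(6, 2))
  expect_equal(h$`train-test`$n_pairs, 6 * 4)
  for (cl in c("train-train", "test-test", "train-test")) {
    area <- sum(h[[cl]]$density * diff(h$breaks))
    expect_equal(area, 1)
  }
  # all-identical items put every pair at similarity 1
  same <- matrix(rep(c(1, 0, 1, 0), 6), 6, byrow = TRUE,
                 dimnames = list(paste0("s", 1:6), NULL))
  gs <- setNames(rep(c("train", "test"), 3), rownames(same))
  hs <- pairwise_similarity_histogram(same, gs)
  last_bin <- length(hs$breaks) - 1L
  expect_equal(hs$`train-train`$counts[last_bin], hs$`train-train`$n_pairs)
  expect_error(pairwise_similarity_histogram(
    items, setNames(rep("train", 10), rownames(items))), "empty group")
})

test_that("2-D embeddings separate well-separated blobs", {
  set.seed(94)
  blob1 <- matrix(rnorm(30 * 5), 30)
  blob2 <- matrix(rnorm(30 * 5, mean = 10), 30)
  X <- rbind(blob1, blob2)
  rownames(X) <- paste0("i", 1:60)
  coords <- embed_2d(X)
  expect_equal(dim(coords), c(60L, 2L))
  labels <- rep(c(1, 2), each = 30)
  expect_gt(oracle_silhouette(coords, labels), 0.5)
  expect_identical(embed_2d(X), embed_2d(X))
  expect_error(embed_2d(X[1:3, ]), "at least")
})
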