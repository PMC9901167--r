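# Diagnostics for benchmark datasets and trained models: k-NN
# applicability domain, prediction-agreement matrices, covariate-shift
# tests between folds, pairwise-similarity histograms, and a 2-D
# embedding for visual inspection.

#' k-nearest-neighbour applicability domain scores
#'
#' For each test item, the mean similarity of its `k` most similar
#' training items (all of them when fewer than `k` exist). With binary
#' fingerprints the similarity is Tanimoto; a precomputed similarity
#' matrix (e.g. sequence identities) can be supplied instead. Low scores
#' flag test items outside the model's applicability domain.
#'
#' @param test_items,train_items feature tables / binary matrices with id
#'   rownames (ignored when `similarity` is a matrix).
#' @param k neighbourhood size (default 5).
#' @param similarity `"tanimoto"` or a numeric matrix with test ids as
#'   rows and train ids as columns.
#' @return named numeric vector of mean top-k similarities per test item.
#' @export
knn_ad <- function(test_items, train_items = NULL, k = 5L,
                   similarity = "tanimoto") {
  if (is.character(similarity) && similarity == "tanimoto") {
    if (is.null(train_items) || nrow(as.matrix(train_items)) == 0L) {
      abort("empty training set")
    }
    sim <- tanimoto_matrix(as.matrix(test_items), as.matrix(train_items))
  } else {
    sim <- as.matrix(similarity)
    if (ncol(sim) == 0L) abort("empty training set")
  }
  k_eff <- min(k, ncol(sim))
  out <- apply(sim, 1L, function(s) mean(sort(s, decreasing = TRUE)[seq_len(k_eff)]))
  stats::setNames(as.numeric(out), rownames(sim))
}

#' Applicability-domain report
#'
#' Combines per-record k-NN similarity scores with absolute prediction
#' errors and the fraction of records predicted within `error_threshold`.
#'
#' @param compound_similarity per-record mean k-NN compound similarities
#'   (from [knn_ad()]).
#' @param y_true,y_pred activities and predictions, aligned with the
#'   similarity vector.
#' @param protein_similarity optional per-record protein-side k-NN
#'   similarities.
#' @param error_threshold error considered "reliable" (default 1
#'   pChEMBL unit).
#' @return list of class `ad_report` with per-record values and the
#'   summary fraction.
#' @export
ad_report <- function(compound_similarity, y_true, y_pred,
                      protein_similarity = NULL, error_threshold = 1.0) {
  abs_error <- abs(y_true - y_pred)
  if (length(abs_error) != length(compound_similarity)) {
    abort("similarities and predictions must align")
  }
  structure(list(
    mean_knn_compound_similarity = compound_similarity,
    mean_knn_protein_similarity = protein_similarity,
    abs_error = abs_error,
    reliable_fraction = mean(abs_error < error_threshold),
    error_threshold = error_threshold
  ), class = "ad_report")
}

#' Prediction agreement between two models
#'
#' Percent of records whose two predicted activities fall into the same
#' six-bin class ([activity_bins()]), regardless of correctness.
#'
#' @param pred_a,pred_b prediction vectors over the same records, in the
#'   same order.
#' @return agreement percentage in [0, 100].
#' @export
prediction_agreement <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) {
    abort("prediction vectors must have equal length")
  }
  if (length(pred_a) == 0L) abort("empty prediction vectors")
  100 * mean(activity_bins(pred_a) == activity_bins(pred_b))
}

#' Pairwise prediction-agreement matrix
#'
#' All-pairs [prediction_agreement()] between named models on a shared
#' test set, plus an average-linkage clustering order on
#' (100 - agreement) distances for heatmap display.
#'
#' @param predictions named list of prediction vectors over the same
#'   records, same order.
#' @return list of class `agreement_matrix` with `matrix` (symmetric,
#'   diagonal 100) and `order` (leaf order from clustering).
#' @export
agreement_matrix <- function(predictions) {
  if (length(predictions) < 2L) abort("need at least two models")
  lens <- lengths(predictions)
  if (length(unique(lens)) != 1L) {
    abort("all models must predict the same record set")
  }
  nm <- names(predictions)
  if (is.null(nm) || any(nm == "")) abort("models must be named")
  k <- length(predictions)
  M <- matrix(100, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      M[i, j] <- M[j, i] <- prediction_agreement(predictions[[i]],
                                                 predictions[[j]])
    }
  }
  hc <- stats::hclust(stats::as.dist(100 - M), method = "average")
  structure(list(matrix = M, order = nm[hc$order], hclust = hc),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat(sprintf("<agreement_matrix> %d models, mean off-diagonal agreement %.1f%%\n",
              nrow(x$matrix), mean(x$matrix[upper.tri(x$matrix)])))
  invisible(x)
}

#' Kolmogorov-Smirnov covariate-shift test
#'
#' Two-sample KS distance and asymptotic p-value per feature dimension
#' between the training and test folds of a continuous feature table.
#' Under a random split no dimension should shift beyond the false
#' positive rate; dissimilarity-constrained splits typically shift many.
#'
#' @param train_features,test_features numeric matrices / feature tables
#'   with equal column count.
#' @param alpha significance level (default 0.01).
#' @return list of class `shift_report` with `statistic`, `p_value`,
#'   `n_significant`, `alpha`, `test`.
#' @export
ks_shift <- function(train_features, test_features, alpha = 0.01) {
  A <- as.matrix(train_features)
  B <- as.matrix(test_features)
  if (ncol(A) != ncol(B)) abort("feature dimensions differ")
  if (nrow(A) == 0L || nrow(B) == 0L) abort("folds must be nonempty")
  stat <- numeric(ncol(A))
  pval <- numeric(ncol(A))
  for (j in seq_len(ncol(A))) {
    kt <- suppressWarnings(stats::ks.test(A[, j], B[, j]))
    stat[j] <- unname(kt$statistic)
    pval[j] <- kt$p.value
  }
  structure(list(statistic = stat, p_value = pval,
                 n_significant = sum(pval < alpha), alpha = alpha,
                 test = "ks"),
            class = "shift_report")
}

#' Chi-square covariate-shift test for binary features
#'
#' Per-bit 2x2 contingency test (bit value x fold) without continuity
#' correction. Bits constant across both folds have no defined statistic
#' and are reported as skipped. The default alpha of 0.001 compensates
#' for the sample-size sensitivity of the chi-square test.
#'
#' @param train_bits,test_bits binary matrices / feature tables with
#'   equal column count.
#' @param alpha significance level (default 0.001).
#' @return list of class `shift_report` with `statistic`, `p_value`,
#'   `skipped` (logical per bit), `n_significant`, `alpha`, `test`.
#' @export
chi2_shift <- function(train_bits, test_bits, alpha = 0.001) {
  A <- as.matrix(train_bits)
  B <- as.matrix(test_bits)
  if (ncol(A) != ncol(B)) abort("feature dimensions differ")
  if (nrow(A) == 0L || nrow(B) == 0L) abort("folds must be nonempty")
  p <- ncol(A)
  stat <- rep(NA_real_, p)
  pval <- rep(NA_real_, p)
  skipped <- logical(p)
  for (j in seq_len(p)) {
    vals <- c(A[, j], B[, j])
    if (length(unique(vals)) < 2L) {
      skipped[j] <- TRUE
      next
    }
    tab <- rbind(train = c(sum(A[, j] == 0), sum(A[, j] == 1)),
                 test = c(sum(B[, j] == 0), sum(B[, j] == 1)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat[j] <- unname(ct$statistic)
    pval[j] <- ct$p.value
  }
  structure(list(statistic = stat, p_value = pval, skipped = skipped,
                 n_significant = sum(pval < alpha, na.rm = TRUE),
                 alpha = alpha, test = "chi2"),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("<shift_report> %s test over %d feature(s): %d significant at alpha=%g\n",
              x$test, length(x$statistic), x$n_significant, x$alpha))
  invisible(x)
}

#' Pairwise similarity histograms by fold comparison
#'
#' Density-normalized histograms of unique-pair similarities for
#' train-vs-train, test-vs-test and train-vs-test comparisons. A random
#' item subsample (`sample_fraction`) and a minimum similarity floor can
#' be applied, mirroring how large compound sets are diagnosed.
#'
#' @param items binary fingerprint matrix / feature table (Tanimoto
#'   similarities) or a precomputed square similarity matrix with id
#'   row/colnames.
#' @param groups named character vector id -> `"train"`/`"test"`
#'   covering the item ids.
#' @param breaks histogram breaks (default 20 equal bins over [0, 1]).
#' @param sample_fraction fraction of items sampled per group (default 1).
#' @param min_similarity pairs below this value are dropped (default 0).
#' @param seed integer seed for sampling.
#' @param precomputed set `TRUE` when `items` is already a similarity
#'   matrix.
#' @return list of class `similarity_histogram`: per comparison class,
#'   `counts`, `density` and `n_pairs`.
#' @export
pairwise_similarity_histogram <- function(items, groups,
                                          breaks = seq(0, 1, by = 0.05),
                                          sample_fraction = 1.0,
                                          min_similarity = 0.0,
                                          seed = 1L,
                                          precomputed = FALSE) {
  ids <- if (precomputed) rownames(items) else rownames(as.matrix(items))
  if (!all(ids %in% names(groups))) {
    abort("`groups` must cover every item id")
  }
  groups <- groups[ids]
  for (g in c("train", "test")) {
    if (!any(groups == g)) abort("empty group: %s", g)
  }
  if (sample_fraction < 1) {
    keep <- with_seed(seed, unlist(lapply(c("train", "test"), function(g) {
      g_ids <- ids[groups == g]
      sample(g_ids, max(2L, ceiling(sample_fraction * length(g_ids))))
    })))
    ids <- ids[ids %in% keep]
    groups <- groups[ids]
  }
  sim <- if (precomputed) {
    as.matrix(items)[ids, ids]
  } else {
    tanimoto_matrix(as.matrix(items)[ids, , drop = FALSE])
  }
  ut <- which(upper.tri(sim), arr.ind = TRUE)
  pair_class <- ifelse(
    groups[ut[, 1L]] == groups[ut[, 2L]],
    paste0(groups[ut[, 1L]], "-", groups[ut[, 1L]]),
    "train-test")
  vals <- sim[ut]
  keep <- vals >= min_similarity
  vals <- vals[keep]
  pair_class <- pair_class[keep]
  out <- lapply(c("train-train", "test-test", "train-test"), function(cl) {
    v <- vals[pair_class == cl]
    if (length(v) == 0L) {
      return(list(counts = rep(0L, length(breaks) - 1L),
                  density = rep(0, length(breaks) - 1L), n_pairs = 0L))
    }
    h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    list(counts = h$counts, density = h$density, n_pairs = length(v))
  })
  names(out) <- c("train-train", "test-test", "train-test")
  structure(c(out, list(breaks = breaks)), class = "similarity_histogram")
}

#' 2-D embedding of feature vectors
#'
#' Principal-coordinate (classical multidimensional scaling) embedding of
#' the Euclidean distances between feature vectors, for visual inspection
#' of group and fold structure. Deterministic for a given input; the
#' `seed` is used only to break exact-duplicate ties by an infinitesimal
#' jitter.
#'
#' @param features numeric matrix / feature table with id rownames.
#' @param min_items guard: minimum number of items (default 10).
#' @param seed integer seed.
#' @return numeric matrix (items x 2) of coordinates.
#' @export
embed_2d <- function(features, min_items = 10L, seed = 1L) {
  X <- as.matrix(features)
  if (nrow(X) < min_items) {
    abort("need at least %d items for a 2-D embedding", min_items)
  }
  d <- stats::dist(X)
  if (any(d == 0)) {
    jit <- with_seed(seed, matrix(stats::rnorm(length(X), 0, 1e-9),
                                  nrow = nrow(X)))
    d <- stats::dist(X + jit)
  }
  coords <- stats::cmdscale(d, k = 2L)
  rownames(coords) <- rownames(X)
  coords
}
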