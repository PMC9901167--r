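# Proteochemometric modelling harness: pair-feature assembly
# (protein vector ++ compound vector), random-forest regression with the
# standard PCM hyperparameters, and nested cross-validated classification
# for target feature-based models.

#' Assemble a pair feature matrix
#'
#' Builds the supervised design matrix for a bioactivity table. In
#' `"pcm"` mode each row is the concatenation of the record's protein and
#' compound vectors; `"protein_only"` uses the protein vector alone
#' (target feature-based models); `"compound_only"` the compound vector
#' alone (ligand-information baselines).
#'
#' @param table a [bioactivity_table()].
#' @param protein_features protein [feature_table()] (required unless
#'   mode is `"compound_only"`).
#' @param compound_features compound [feature_table()] (required unless
#'   mode is `"protein_only"`).
#' @param mode `"pcm"`, `"protein_only"` or `"compound_only"`.
#' @return An object of class `pair_matrix`: list with `record_ids`, `X`
#'   (numeric matrix) and `y` (activities).
#' @export
assemble_pcm_matrix <- function(table, protein_features = NULL,
                                compound_features = NULL,
                                mode = c("pcm", "protein_only",
                                         "compound_only")) {
  mode <- match.arg(mode)
  assert_bioactivity_table(table)
  blocks <- list()
  if (mode %in% c("pcm", "protein_only")) {
    if (is.null(protein_features)) abort("mode %s needs protein features", mode)
    missing <- setdiff(unique(table$protein_id), rownames(protein_features))
    if (length(missing)) {
      abort("protein id(s) not covered by the feature table: %s",
            paste(utils::head(missing, 5L), collapse = ", "))
    }
    P <- as.matrix(protein_features)[table$protein_id, , drop = FALSE]
    colnames(P) <- paste0("prot_", seq_len(ncol(P)))
    blocks$protein <- P
  }
  if (mode %in% c("pcm", "compound_only")) {
    if (is.null(compound_features)) abort("mode %s needs compound features", mode)
    missing <- setdiff(unique(table$compound_id), rownames(compound_features))
    if (length(missing)) {
      abort("compound id(s) not covered by the feature table: %s",
            paste(utils::head(missing, 5L), collapse = ", "))
    }
    C <- as.matrix(compound_features)[table$compound_id, , drop = FALSE]
    colnames(C) <- paste0("cmp_", seq_len(ncol(C)))
    blocks$compound <- C
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- NULL
  structure(list(record_ids = table$record_id, X = X, y = table$activity),
            class = "pair_matrix")
}

#' Subset a pair matrix by row index
#'
#' @param m a `pair_matrix` from [assemble_pcm_matrix()].
#' @param idx integer row indices (positions, not record ids).
#' @return the subsetted `pair_matrix`.
#' @export
subset_pair_matrix <- function(m, idx) {
  structure(list(record_ids = m$record_ids[idx],
                 X = m$X[idx, , drop = FALSE],
                 y = m$y[idx]),
            class = "pair_matrix")
}

#' Train a PCM random-forest regressor
#'
#' Random forest with 100 trees and one third of the features tried per
#' split, the standard PCM regression setting.
#'
#' @param matrix a [assemble_pcm_matrix()] pair matrix with real-valued
#'   activities.
#' @param ntree number of trees (default 100).
#' @param mtry_fraction fraction of columns tried per split
#'   (default 1/3).
#' @param seed integer seed.
#' @return object of class `pcm_rf` wrapping the forest.
#' @export
train_rf_regressor <- function(matrix, ntree = 100L, mtry_fraction = 0.33,
                               seed = 1L) {
  stopifnot(inherits(matrix, "pair_matrix"))
  if (nrow(matrix$X) < 5L) abort("need at least 5 training rows")
  if (!is.numeric(matrix$y)) abort("regression needs numeric activities")
  mtry <- max(1L, floor(mtry_fraction * ncol(matrix$X)))
  fit <- with_seed(seed, randomForest::randomForest(
    x = matrix$X, y = matrix$y, ntree = ntree, mtry = mtry))
  structure(list(fit = fit, p = ncol(matrix$X), ntree = ntree,
                 mtry = mtry, seed = seed),
            class = "pcm_rf")
}

#' @export
print.pcm_rf <- function(x, ...) {
  cat(sprintf("<pcm_rf> %d trees, mtry=%d over %d features\n",
              x$ntree, x$mtry, x$p))
  invisible(x)
}

#' Predict from a PCM random forest
#'
#' @param object a `pcm_rf` model.
#' @param newdata a `pair_matrix` or numeric matrix with the training
#'   column count.
#' @param ... unused.
#' @return numeric prediction vector aligned with the input rows.
#' @export
predict.pcm_rf <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "pair_matrix")) newdata$X else as.matrix(newdata)
  if (ncol(X) != object$p) {
    abort("feature count mismatch: model has %d columns, input has %d",
          object$p, ncol(X))
  }
  as.numeric(stats::predict(object$fit, X))
}

# stratified k-fold assignment (returns fold index per row)
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# fit one classifier spec and return predicted labels for test rows
fit_predict_classifier <- function(X_train, y_train, X_test, algorithm,
                                   params, seed) {
  if (algorithm == "random_forest") {
    mtry <- max(1L, floor(sqrt(ncol(X_train))))
    fit <- with_seed(seed, randomForest::randomForest(
      x = X_train, y = factor(y_train, levels = c(0L, 1L)),
      ntree = params$ntree %||% 200L, mtry = mtry))
    as.integer(as.character(stats::predict(fit, X_test)))
  } else {
    # standardize on the training portion only; constant columns are
    # left unscaled
    mu <- colMeans(X_train)
    sdev <- apply(X_train, 2L, stats::sd)
    sdev[sdev == 0] <- 1
    Xs <- scale(X_train, mu, sdev)
    Xt <- scale(X_test, mu, sdev)
    fit <- with_seed(seed, e1071::svm(
      x = Xs, y = factor(y_train, levels = c(0L, 1L)),
      kernel = "radial", cost = params$cost, gamma = params$gamma,
      scale = FALSE))
    as.integer(as.character(stats::predict(fit, Xt)))
  }
}

default_grid <- function(algorithm) {
  if (algorithm == "random_forest") {
    data.frame(ntree = 200L)
  } else {
    expand.grid(cost = c(1, 10, 100), gamma = c(0.001, 0.01, 0.1, 1))
  }
}

#' Nested cross-validated classification
#'
#' Target feature-based binary classification with stratified outer folds
#' for testing and an inner cross-validation grid search for
#' hyperparameter selection. The inner selection criterion is mean MCC;
#' outer-fold metrics are computed on untouched folds and averaged.
#' Default grids: random forest with 200 trees and sqrt(p) features per
#' split (single point); RBF-kernel SVM over cost {1, 10, 100} x gamma
#' {0.001, 0.01, 0.1, 1}, with features standardized on each training
#' portion.
#'
#' @param matrix a `pair_matrix` whose `y` holds binary 0/1 labels.
#' @param algorithm `"random_forest"` or `"svm_rbf"`.
#' @param inner_folds inner loop folds (default 10).
#' @param outer_folds outer loop folds (default 5).
#' @param grid data frame of hyperparameter combinations; `NULL` for the
#'   algorithm default.
#' @param seed integer seed.
#' @return list with `per_fold` (metric list per outer fold), `aggregate`
#'   (mean over outer folds), `chosen` (selected grid row per fold).
#' @export
nested_cv_classify <- function(matrix, algorithm = c("random_forest",
                                                     "svm_rbf"),
                               inner_folds = 10L, outer_folds = 5L,
                               grid = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(matrix, "pair_matrix"))
  y <- as.integer(matrix$y)
  if (!all(y %in% c(0L, 1L))) abort("labels must be binary (0/1)")
  if (min(table(y)) < outer_folds) {
    abort("need at least %d samples per class for %d stratified outer folds",
          outer_folds, outer_folds)
  }
  grid <- grid %||% default_grid(algorithm)
  outer <- stratified_folds(y, outer_folds, seed)
  per_fold <- vector("list", outer_folds)
  chosen <- vector("list", outer_folds)
  for (of in seq_len(outer_folds)) {
    tr <- which(outer != of)
    te <- which(outer == of)
    # inner grid search on the outer-training portion
    best_row <- 1L
    if (nrow(grid) > 1L) {
      inner_k <- min(inner_folds, min(table(y[tr])))
      inner <- stratified_folds(y[tr], inner_k, seed + of)
      mean_mcc <- vapply(seq_len(nrow(grid)), function(gi) {
        mccs <- vapply(seq_len(inner_k), function(inf) {
          itr <- tr[inner != inf]
          ite <- tr[inner == inf]
          pred <- fit_predict_classifier(
            matrix$X[itr, , drop = FALSE], y[itr],
            matrix$X[ite, , drop = FALSE], algorithm,
            as.list(grid[gi, , drop = FALSE]), seed + 31L * gi + inf)
          classification_metrics(confusion_counts(y[ite], pred))$mcc
        }, numeric(1))
        mean(mccs)
      }, numeric(1))
      best_row <- which.max(mean_mcc)
    }
    chosen[[of]] <- grid[best_row, , drop = FALSE]
    pred <- fit_predict_classifier(
      matrix$X[tr, , drop = FALSE], y[tr],
      matrix$X[te, , drop = FALSE], algorithm,
      as.list(grid[best_row, , drop = FALSE]), seed + 1000L + of)
    per_fold[[of]] <- classification_metrics(confusion_counts(y[te], pred))
  }
  metric_names <- names(per_fold[[1L]])
  aggregate <- stats::setNames(lapply(metric_names, function(mn) {
    mean(vapply(per_fold, `[[`, numeric(1), mn))
  }), metric_names)
  list(per_fold = per_fold, aggregate = aggregate, chosen = chosen)
}
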