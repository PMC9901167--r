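# Performance metrics for DTI prediction: standard classification scores,
# regression scores, and the corrected variants (median-corrected RMSE/MCC,
# six-bin multiclass MCC) designed to diagnose systematically shifted
# regression outputs.

#' Confusion counts from binary labels
#'
#' @param y_true,y_pred binary vectors (0/1 or logical) of equal length.
#' @return An object of class `confusion_counts`: a named list with
#'   integer fields `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length (%d vs %d)",
          length(y_true), length(y_pred))
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    abort("labels must be binary (0/1)")
  }
  structure(list(
    TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, recall, precision, F1 and the Matthews correlation
#' coefficient. Any score whose denominator is zero is reported as 0 by
#' convention (degenerate confusion matrices).
#'
#' @param counts a `confusion_counts` object, or a numeric vector/list with
#'   named elements `TP`, `TN`, `FP`, `FN`.
#' @return A named list with fields `accuracy`, `recall`, `precision`,
#'   `f1`, `mcc`.
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, 1, 0, 0, 0),
#'                                         c(1, 1, 0, 0, 0, 1)))
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, tn, fp, fn) < 0) || any(!is.finite(c(tp, tn, fp, fn)))) {
    abort("confusion counts must be non-negative finite numbers")
  }
  accuracy <- safe_div(tp + tn, tp + tn + fp + fn)
  recall <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe_div(tp * tn - fp * fn, mcc_den)
  list(accuracy = accuracy, recall = recall, precision = precision,
       f1 = f1, mcc = mcc)
}

#' Root mean square error
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return sqrt(mean((y_true - y_pred)^2)).
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length")
  }
  if (length(y_true) < 1L) abort("need at least one observation")
  sqrt(mean((y_true - y_pred)^2))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values; for tie-free data this
#' equals the classical 1 - 6*sum(D^2)/(n(n^2-1)) form.
#'
#' @param y_true,y_pred numeric vectors of equal length, n >= 2.
#' @return correlation in [-1, 1].
#' @export
spearman_rho <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length")
  }
  if (length(y_true) < 2L) abort("Spearman correlation needs n >= 2")
  if (stats::var(y_true) == 0 || stats::var(y_pred) == 0) {
    abort("Spearman correlation undefined for a constant vector")
  }
  stats::cor(rank(y_true), rank(y_pred), method = "pearson")
}

#' Binarize activities at a cut-off
#'
#' A value is labelled active (1) iff strictly greater than `cutoff`;
#' values equal to the cut-off are inactive (0). With pChEMBL/pKd inputs
#' this matches the "active above 5 / above the training median" rule.
#'
#' @param values numeric vector of activities.
#' @param cutoff activity threshold (same units as `values`).
#' @return integer vector of 0/1 labels.
#' @export
binarize <- function(values, cutoff) {
  if (any(!is.finite(values))) abort("activities must be finite")
  as.integer(values > cutoff)
}

#' Median-shift predictions onto the true-value median
#'
#' Adds the constant `median(y_true) - median(y_pred)` to every prediction
#' so the prediction median equals the truth median exactly. Rank-based
#' scores are unchanged by this shift; value-based scores computed after it
#' ("median-corrected") are insensitive to a systematic offset of the model
#' output.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return the shifted prediction vector.
#' @export
median_shift <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length")
  }
  if (length(y_true) < 1L) abort("need at least one observation")
  y_pred + (stats::median(y_true) - stats::median(y_pred))
}

#' Median-corrected RMSE
#'
#' RMSE computed after [median_shift()].
#'
#' @inheritParams median_shift
#' @return non-negative number.
#' @export
median_corrected_rmse <- function(y_true, y_pred) {
  rmse(y_true, median_shift(y_true, y_pred))
}

#' Median-corrected MCC
#'
#' Predictions are median-shifted, then both vectors are binarized at
#' `cutoff` and the Matthews correlation coefficient is computed.
#'
#' @inheritParams median_shift
#' @param cutoff activity threshold used for binarization.
#' @return MCC in [-1, 1].
#' @export
median_corrected_mcc <- function(y_true, y_pred, cutoff) {
  shifted <- median_shift(y_true, y_pred)
  m <- classification_metrics(
    confusion_counts(binarize(y_true, cutoff), binarize(shifted, cutoff)))
  m$mcc
}

#' Six-bin activity classes
#'
#' Bins pChEMBL/pKd values into six classes: (-Inf,5), [5,5.5), [5.5,6),
#' [6,6.5), [6.5,7), [7,Inf). Interval bounds are lower-inclusive.
#'
#' @param values numeric activities.
#' @return integer class labels 1..6.
#' @export
activity_bins <- function(values) {
  if (any(!is.finite(values))) abort("activities must be finite")
  as.integer(cut(values, breaks = c(-Inf, 5, 5.5, 6, 6.5, 7, Inf),
                 right = FALSE, labels = FALSE))
}

#' Multiclass (six-bin) MCC
#'
#' True and predicted activities are binned with [activity_bins()]; a
#' one-vs-rest binary MCC is computed per class (0 for degenerate classes)
#' and the unweighted mean over the six classes is returned. More
#' restrictive than single-threshold MCC since predictions must land in
#' narrow half-unit intervals.
#'
#' @inheritParams median_shift
#' @param method `"macro"` (mean of one-vs-rest MCCs, the default) or
#'   `"rk"` for the single multi-category correlation (Gorodkin's Rk).
#' @return score in [-1, 1].
#' @export
multiclass_mcc <- function(y_true, y_pred, method = c("macro", "rk")) {
  method <- match.arg(method)
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length")
  }
  if (length(y_true) < 2L) abort("multiclass MCC needs n >= 2")
  bt <- activity_bins(y_true)
  bp <- activity_bins(y_pred)
  if (method == "macro") {
    per_class <- vapply(1:6, function(k) {
      m <- classification_metrics(
        confusion_counts(as.integer(bt == k), as.integer(bp == k)))
      m$mcc
    }, numeric(1))
    return(mean(per_class))
  }
  # Gorodkin Rk over the 6x6 contingency table
  n <- length(bt)
  C <- table(factor(bt, levels = 1:6), factor(bp, levels = 1:6))
  C <- matrix(as.numeric(C), 6, 6)
  t_k <- rowSums(C)  # true class totals
  p_k <- colSums(C)  # predicted class totals
  num <- n * sum(diag(C)) - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  safe_div(num, den)
}

#' Regression metric report
#'
#' Convenience wrapper computing the full regression-side report used for
#' PCM models: RMSE, Spearman, median-corrected RMSE/MCC at a cut-off, and
#' six-bin multiclass MCC.
#'
#' @inheritParams median_shift
#' @param cutoff activity threshold for the binary scores; defaults to the
#'   median of `y_true`.
#' @return named list of scores.
#' @export
regression_metrics <- function(y_true, y_pred, cutoff = stats::median(y_true)) {
  cls <- classification_metrics(
    confusion_counts(binarize(y_true, cutoff), binarize(y_pred, cutoff)))
  list(
    rmse = rmse(y_true, y_pred),
    spearman = spearman_rho(y_true, y_pred),
    mcc = cls$mcc,
    f1 = cls$f1,
    median_corrected_rmse = median_corrected_rmse(y_true, y_pred),
    median_corrected_mcc = median_corrected_mcc(y_true, y_pred, cutoff),
    multiclass_mcc = multiclass_mcc(y_true, y_pred)
  )
}
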