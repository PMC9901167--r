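# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops over definitions) so they cannot
# share a code path with the implementation they check.

# confusion counts by explicit looping
oracle_confusion <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

oracle_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# six-bin class of one value, by explicit comparisons
oracle_bin <- function(v) {
  if (v < 5) 1L
  else if (v < 5.5) 2L
  else if (v < 6) 3L
  else if (v < 6.5) 4L
  else if (v < 7) 5L
  else 6L
}

# macro-averaged six-bin MCC by looping over classes
oracle_multiclass_mcc <- function(y_true, y_pred) {
  bt <- vapply(y_true, oracle_bin, integer(1))
  bp <- vapply(y_pred, oracle_bin, integer(1))
  mccs <- numeric(6)
  for (k in 1:6) {
    cc <- oracle_confusion(as.integer(bt == k), as.integer(bp == k))
    mccs[k] <- oracle_mcc(cc["TP"], cc["TN"], cc["FP"], cc["FN"])
  }
  mean(mccs)
}

# Spearman via the classical rank-difference formula (tie-free inputs)
oracle_spearman_no_ties <- function(y_true, y_pred) {
  d <- rank(y_true) - rank(y_pred)
  n <- length(y_true)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Tanimoto by explicit bit loop
oracle_tanimoto <- function(a, b) {
  inter <- 0
  un <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    if (a[i] == 1 || b[i] == 1) un <- un + 1
  }
  if (un == 0) 0 else inter / un
}

# two-sample KS distance as the sup difference of empirical CDFs,
# evaluated at every pooled point
oracle_ks_distance <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- 0
  for (p in pts) {
    d <- max(d, abs(mean(x <= p) - mean(y <= p)))
  }
  d
}

# O(n^2) cross-fold leakage scan; returns violation counts
oracle_leakage <- function(table, split, fingerprints, clusters = NULL,
                           threshold = 0.5) {
  train_rows <- table[table$record_id %in% split$train, ]
  test_rows <- table[table$record_id %in% split$test, ]
  fp <- as.matrix(fingerprints)
  cmp_viol <- 0L
  for (a in unique(train_rows$compound_id)) {
    for (b in unique(test_rows$compound_id)) {
      if (oracle_tanimoto(fp[a, ], fp[b, ]) >= threshold) {
        cmp_viol <- cmp_viol + 1L
      }
    }
  }
  prot_viol <- 0L
  if (!is.null(clusters)) {
    cl <- unclass(clusters)
    for (a in unique(train_rows$protein_id)) {
      for (b in unique(test_rows$protein_id)) {
        if (cl[[a]] == cl[[b]]) prot_viol <- prot_viol + 1L
      }
    }
  }
  list(compound = cmp_viol, protein = prot_viol)
}

# mean silhouette width of a 2-group labelling on coordinates
oracle_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  s <- numeric(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- mean(d[i, !own])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# naive per-entity evaluation of the uninformativeness rules; one pass
# flags entities of the given table, iterate = TRUE repeats to a fixed
# point; returns the surviving record ids
oracle_uninformative <- function(tab, thr, ratio_cap = 4, min_sd = 0.3,
                                 iterate = TRUE) {
  df <- as.data.frame(tab)
  repeat {
    bad <- integer(0)
    for (side in c("compound_id", "protein_id")) {
      for (ent in unique(df[[side]])) {
        acts <- df$activity[df[[side]] == ent]
        n_act <- sum(acts > thr)
        n_inact <- length(acts) - n_act
        fires <- n_act == 0 || n_inact == 0 ||
          n_act / n_inact > ratio_cap || n_act / n_inact < 1 / ratio_cap ||
          (length(acts) >= 2 && sd(acts) < min_sd)
        if (fires) bad <- union(bad, df$record_id[df[[side]] == ent])
      }
    }
    df <- df[!(df$record_id %in% bad), , drop = FALSE]
    if (!iterate || length(bad) == 0 || nrow(df) == 0) break
  }
  df$record_id
}

# small deterministic bioactivity table
toy_table <- function() {
  bioactivity_table(
    compound_id = c("c1", "c2", "c1", "c3", "c2"),
    protein_id = c("p1", "p1", "p2", "p2", "p3"),
    activity = c(6.0, 5.2, 7.1, 4.8, 6.6))
}
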