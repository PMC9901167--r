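# Bioactivity dataset filters: removal of assay-floor censored values,
# removal of uninformative compounds/targets from training folds, and the
# compound-centric dataset builder with similarity-constrained negative
# augmentation.

new_filter_report <- function(removed_censored = integer(0),
                              removed_by_rule = list(),
                              threshold_used = NA_real_) {
  structure(list(removed_censored = removed_censored,
                 removed_by_rule = removed_by_rule,
                 threshold_used = threshold_used),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d censored record(s) removed; threshold %.4g\n",
              length(x$removed_censored), x$threshold_used))
  for (rule in names(x$removed_by_rule)) {
    r <- x$removed_by_rule[[rule]]
    cat(sprintf("  rule %s: %d entit%s, %d record(s)\n", rule,
                length(r$entities), if (length(r$entities) == 1) "y" else "ies",
                length(r$record_ids)))
  }
  invisible(x)
}

#' Remove censored (assay-floor) activities
#'
#' Records whose activity equals the assay floor (within 1e-9) are
#' removed. In Davis-style Kd panels, pairs with no response at the
#' maximum dose are recorded at the dose itself (pKd = 5); such values
#' are dose limits, not affinities, and bias regression models toward
#' predicting the floor.
#'
#' @param table a [bioactivity_table()].
#' @param floor the censoring value (default 5.0 pChEMBL/pKd).
#' @return list with `table` (filtered, record ids preserved) and
#'   `report` (a `filter_report`).
#' @export
filter_censored <- function(table, floor = 5.0) {
  assert_bioactivity_table(table)
  censored <- abs(table$activity - floor) <= 1e-9
  out <- table[!censored, , drop = FALSE]
  class(out) <- c("bioactivity_table", "data.frame")
  list(table = out,
       report = new_filter_report(
         removed_censored = table$record_id[censored],
         threshold_used = floor))
}

# evaluate the three uninformativeness rules for one entity's activities;
# returns the first firing rule id ("a", "b", "c") or NA
first_firing_rule <- function(acts, threshold, ratio_cap, min_sd) {
  n_active <- sum(acts > threshold)
  n_inactive <- length(acts) - n_active
  if (n_active == 0L || n_inactive == 0L) return("a")
  ratio <- n_active / n_inactive
  if (ratio > ratio_cap || ratio < 1 / ratio_cap) return("b")
  if (length(acts) >= 2L && stats::sd(acts) < min_sd) return("c")
  NA_character_
}

#' Remove uninformative compounds and targets from a training fold
#'
#' Every compound and every target is marked for removal if (a) all of
#' its activities lie on one side of the activity threshold, (b) its
#' active-to-inactive ratio exceeds `ratio_cap` (or falls below its
#' reciprocal), or (c) the sample standard deviation of its activities
#' is below `min_sd` (values vary within a narrow range). All records of
#' marked entities are removed; such entities are predictable by
#' memorization and contribute nothing to learning. Because removing one
#' entity's records can turn a surviving entity one-sided, the
#' simultaneous marking pass is repeated until no rule fires, which
#' makes the filter idempotent; the first pass alone removes exactly
#' what an independent per-entity evaluation of the input table flags.
#' Removal is attributed to the first firing rule (a, b, c) per entity.
#'
#' @param table a [bioactivity_table()] (training fold).
#' @param threshold activity threshold separating actives from
#'   inactives, or `"median"` to use the median activity of `table`.
#' @param ratio_cap active/inactive ratio cap (default 4).
#' @param min_sd minimum per-entity activity standard deviation
#'   (default 0.3).
#' @return list with `table` (filtered) and `report`.
#' @export
filter_uninformative <- function(table, threshold = "median",
                                 ratio_cap = 4.0, min_sd = 0.3) {
  assert_bioactivity_table(table)
  if (nrow(table) == 0L) abort("cannot filter an empty table")
  thr <- if (identical(threshold, "median")) {
    stats::median(table$activity)
  } else {
    as.numeric(threshold)
  }
  removed <- list(a = list(entities = character(0), record_ids = integer(0)),
                  b = list(entities = character(0), record_ids = integer(0)),
                  c = list(entities = character(0), record_ids = integer(0)))
  current <- table
  repeat {
    marked_records <- integer(0)
    for (side in c("compound_id", "protein_id")) {
      for (ent in unique(current[[side]])) {
        rows <- current[[side]] == ent
        rule <- first_firing_rule(current$activity[rows], thr, ratio_cap,
                                  min_sd)
        if (!is.na(rule)) {
          removed[[rule]]$entities <- union(removed[[rule]]$entities, ent)
          removed[[rule]]$record_ids <- union(removed[[rule]]$record_ids,
                                              current$record_id[rows])
          marked_records <- union(marked_records, current$record_id[rows])
        }
      }
    }
    if (length(marked_records) == 0L) break
    current <- current[!(current$record_id %in% marked_records), ,
                       drop = FALSE]
    if (nrow(current) == 0L) break
  }
  # attribute each record to its first-firing rule only
  removed$b$record_ids <- setdiff(removed$b$record_ids, removed$a$record_ids)
  removed$c$record_ids <- setdiff(removed$c$record_ids,
                                  c(removed$a$record_ids, removed$b$record_ids))
  class(current) <- c("bioactivity_table", "data.frame")
  list(table = current,
       report = new_filter_report(removed_by_rule = removed,
                                  threshold_used = thr))
}

#' Build a compound-centric classification dataset
#'
#' Collects the cluster of compounds within Tanimoto `member_threshold`
#' of a center compound, pools their bioactivity records per protein,
#' aggregates by median, and labels each protein active (aggregated
#' activity > `active_cutoff`) or inactive (<= cutoff). The resulting
#' protein set is the instance universe for target feature-based
#' classification.
#'
#' @param center compound id of the cluster center.
#' @param fingerprints binary fingerprint matrix/[feature_table()]
#'   covering the center and candidate members.
#' @param table a [bioactivity_table()].
#' @param member_threshold Tanimoto threshold for cluster membership
#'   (default 0.3, center always included).
#' @param active_cutoff pChEMBL activity cut-off (default 5.0).
#' @return An object of class `compound_centric_dataset`: list with
#'   `center_id`, `member_ids`, `positives`, `negatives`,
#'   `protein_activity` (named aggregated activities).
#' @export
build_compound_centric <- function(center, fingerprints, table,
                                   member_threshold = 0.3,
                                   active_cutoff = 5.0) {
  assert_bioactivity_table(table)
  fp <- as.matrix(fingerprints)
  if (!center %in% rownames(fp)) {
    abort("unknown center compound: %s", center)
  }
  sims <- tanimoto_matrix(fp[center, , drop = FALSE], fp)[1L, ]
  members <- names(sims)[sims >= member_threshold]
  members <- union(center, members)
  rows <- table[table$compound_id %in% members, , drop = FALSE]
  agg <- tapply(rows$activity, rows$protein_id, stats::median)
  positives <- names(agg)[agg > active_cutoff]
  negatives <- names(agg)[agg <= active_cutoff]
  structure(list(center_id = center,
                 member_ids = members,
                 positives = positives,
                 negatives = negatives,
                 protein_activity = stats::setNames(as.numeric(agg),
                                                    names(agg))),
            class = "compound_centric_dataset")
}

#' @export
print.compound_centric_dataset <- function(x, ...) {
  cat(sprintf(
    "<compound_centric_dataset> center %s: %d member compound(s), %d positive / %d negative protein(s)\n",
    x$center_id, length(x$member_ids), length(x$positives),
    length(x$negatives)))
  invisible(x)
}

#' Augment negatives under similarity constraints
#'
#' Candidate proteins are iterated in a seeded random order; a candidate
#' joins the negative set iff its maximum similarity to the current
#' positives is below `pos_max` and to the current negatives (including
#' negatives added earlier in the iteration) below `neg_max`. Iteration
#' stops when the negative set reaches the size of the positive set.
#' This balances classes without risking mislabelled positives the way
#' unconstrained random sampling would.
#'
#' @param dataset a [build_compound_centric()] dataset.
#' @param protein_sim similarity matrix (percent identity, 0-100) whose
#'   rows/columns cover candidates and current members.
#' @param candidates protein ids to consider.
#' @param pos_max maximum allowed similarity to positives (default 50).
#' @param neg_max maximum allowed similarity to negatives (default 80).
#' @param seed integer seed for the candidate order.
#' @return the dataset with augmented `negatives`.
#' @export
augment_negatives <- function(dataset, protein_sim, candidates,
                              pos_max = 50, neg_max = 80, seed = 1L) {
  stopifnot(inherits(dataset, "compound_centric_dataset"))
  sim <- as.matrix(protein_sim)
  missing <- c(setdiff(candidates, rownames(sim)),
               setdiff(c(dataset$positives, dataset$negatives, candidates),
                       colnames(sim)))
  if (length(missing)) {
    abort("similarity matrix does not cover: %s",
          paste(utils::head(unique(missing), 5L), collapse = ", "))
  }
  lookup <- function(a, b) {
    if (length(b) == 0L) return(-Inf)
    max(sim[a, b])
  }
  candidates <- setdiff(candidates, c(dataset$positives, dataset$negatives))
  order <- with_seed(seed, sample(candidates))
  negatives <- dataset$negatives
  for (cand in order) {
    if (length(negatives) >= length(dataset$positives)) break
    if (lookup(cand, dataset$positives) < pos_max &&
        lookup(cand, negatives) < neg_max) {
      negatives <- c(negatives, cand)
    }
  }
  if (length(negatives) < length(dataset$positives)) {
    warning(sprintf(
      "could not balance classes: %d negatives vs %d positives",
      length(negatives), length(dataset$positives)), call. = FALSE)
  }
  dataset$negatives <- negatives
  dataset
}
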