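# The canonical in-memory bioactivity container: one row per unique
# (compound, protein) pair with a pChEMBL/pKd activity, plus readers and
# split writers.

#' Build a bioactivity table
#'
#' Normalizes raw (compound, protein, activity) rows into the canonical
#' table: duplicate (compound, protein) pairs are aggregated by the median
#' of their activities, first-occurrence row order is preserved, and
#' records are numbered 1..n.
#'
#' @param compound_id,protein_id character vectors.
#' @param activity numeric vector of pChEMBL/pKd values (-log10 molar).
#' @param smiles optional character vector of compound SMILES.
#' @return A data frame of class `bioactivity_table` with columns
#'   `record_id`, `compound_id`, `protein_id`, `activity` (and `smiles`
#'   when supplied).
#' @export
bioactivity_table <- function(compound_id, protein_id, activity,
                              smiles = NULL) {
  compound_id <- as.character(compound_id)
  protein_id <- as.character(protein_id)
  activity <- as.numeric(activity)
  n <- length(activity)
  if (length(compound_id) != n || length(protein_id) != n) {
    abort("compound_id, protein_id and activity must have equal length")
  }
  if (any(is.na(compound_id) | compound_id == "") ||
      any(is.na(protein_id) | protein_id == "")) {
    abort("compound_id and protein_id must be nonempty")
  }
  if (any(!is.finite(activity))) {
    abort("activity values must be finite, offending row(s): %s",
          paste(utils::head(which(!is.finite(activity)), 5L), collapse = ", "))
  }
  key <- paste(compound_id, protein_id, sep = "\r")
  first <- !duplicated(key)
  agg <- tapply(activity, key, stats::median)
  df <- data.frame(
    record_id = seq_len(sum(first)),
    compound_id = compound_id[first],
    protein_id = protein_id[first],
    activity = as.numeric(agg[key[first]]),
    stringsAsFactors = FALSE
  )
  if (!is.null(smiles)) df$smiles <- as.character(smiles)[first]
  class(df) <- c("bioactivity_table", "data.frame")
  df
}

#' @export
print.bioactivity_table <- function(x, ...) {
  cat(sprintf(
    "<bioactivity_table> %d records, %d compounds, %d proteins\n",
    nrow(x), length(unique(x$compound_id)), length(unique(x$protein_id))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more records\n", nrow(x) - 6L))
  invisible(x)
}

assert_bioactivity_table <- function(table) {
  if (!inherits(table, "bioactivity_table")) {
    abort("expected a bioactivity_table (see `bioactivity_table()`)")
  }
  invisible(table)
}

#' Read a delimited bioactivity table
#'
#' Expects a header with compound id, protein id and activity columns.
#' The activity column is recognized under the names `pchembl_value`,
#' `pkd` or `activity` (first match wins); a `smiles` column is optional.
#' Comma- or tab-delimited (sniffed from the first line). Duplicate
#' (compound, protein) pairs are aggregated by median activity.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` to auto-detect.
#' @return a [bioactivity_table()].
#' @export
read_bioactivity_table <- function(path, sep = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  nm <- tolower(names(df))
  ccol <- match(TRUE, nm %in% c("compound_id", "compound", "molecule_chembl_id"))
  pcol <- match(TRUE, nm %in% c("protein_id", "target_id", "protein",
                                "target_chembl_id"))
  acol <- match(TRUE, nm %in% c("pchembl_value", "pkd", "activity"))
  if (is.na(ccol) || is.na(pcol) || is.na(acol)) {
    abort(paste0("bioactivity table %s must contain compound id, protein id ",
                 "and activity columns (pchembl_value/pkd/activity)"), path)
  }
  act_raw <- df[[acol]]
  act <- suppressWarnings(as.numeric(act_raw))
  if (any(is.na(act))) {
    bad <- which(is.na(act))[1L]
    abort("non-numeric activity \"%s\" at data row %d of %s",
          act_raw[bad], bad, path)
  }
  scol <- match(TRUE, nm == "smiles")
  bioactivity_table(df[[ccol]], df[[pcol]], act,
                    smiles = if (!is.na(scol)) df[[scol]] else NULL)
}

#' Read a protein cluster-membership map
#'
#' Two-column delimited file (protein id, cluster id), UniRef50 style; a
#' header line is detected and skipped when its first field is one of
#' `protein_id`/`protein`/`id`. Proteins in the same cluster are treated
#' as similar by the splitters.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` to auto-detect.
#' @return a named character vector (names: protein ids, values: cluster
#'   ids) of class `cluster_map`.
#' @export
read_cluster_map <- function(path, sep = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(stats::setNames(character(0), character(0)),
                     class = "cluster_map"))
  }
  sep <- sep %||% (if (grepl("\t", lines[[1L]])) "\t" else ",")
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort("cluster map %s must have exactly two columns per row", path)
  }
  prot <- trimws(vapply(parts, `[[`, character(1), 1L))
  clus <- trimws(vapply(parts, `[[`, character(1), 2L))
  if (tolower(prot[1L]) %in% c("protein_id", "protein", "id")) {
    prot <- prot[-1L]
    clus <- clus[-1L]
  }
  cluster_map(stats::setNames(clus, prot))
}

#' Construct a cluster map from a named vector
#'
#' @param assignments named character vector: protein id -> cluster id.
#'   Repeated protein ids with conflicting clusters raise an error;
#'   consistent repeats are deduplicated.
#' @return object of class `cluster_map`.
#' @export
cluster_map <- function(assignments) {
  prot <- names(assignments)
  if (is.null(prot) || any(prot == "")) {
    abort("cluster assignments must be named by protein id")
  }
  dup <- duplicated(prot)
  if (any(dup)) {
    for (p in unique(prot[dup])) {
      if (length(unique(assignments[prot == p])) > 1L) {
        abort("protein %s is assigned to more than one cluster", p)
      }
    }
    assignments <- assignments[!dup]
  }
  structure(as.character(assignments), names = names(assignments),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %d proteins in %d clusters\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' The record id is the first whitespace-delimited token of the header.
#' Sequences are uppercased; entries with more than 10% non-canonical
#' residues are rejected with an error, otherwise non-canonical residues
#' are dropped with a warning.
#'
#' @param path FASTA file path.
#' @param max_noncanonical maximum tolerated fraction of non-canonical
#'   residues per entry (default 0.1).
#' @return named character vector of sequences (names: protein ids).
#' @export
read_fasta <- function(path, max_noncanonical = 0.1) {
  if (!file.exists(path)) abort("file not found: %s", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) abort("malformed FASTA %s: %s", path,
                                            conditionMessage(e)))
  if (length(set) == 0L) abort("FASTA file %s contains no sequences", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  out <- stats::setNames(character(length(seqs)), ids)
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[[i]], "")[[1L]]
    bad <- !(res %in% AA20)
    if (mean(bad) > max_noncanonical) {
      abort("entry %s rejected: %.0f%% non-canonical residues",
            ids[[i]], 100 * mean(bad))
    }
    if (any(bad)) {
      warning(sprintf("entry %s: dropped %d non-canonical residue(s)",
                      ids[[i]], sum(bad)), call. = FALSE)
      res <- res[!bad]
    }
    out[[i]] <- paste(res, collapse = "")
  }
  out
}

#' Write the folds of a split to disk
#'
#' Writes `train.csv`, `test.csv` and `discarded.csv` (original columns
#' plus a `fold` label) and a `manifest.json` with fold sizes and the
#' split parameters. Each fold file round-trips through
#' [read_bioactivity_table()].
#'
#' @param table a [bioactivity_table()].
#' @param split a `split_result` partitioning `table`'s record ids.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split <- function(table, split, dir) {
  assert_bioactivity_table(table)
  assert_split_result(split, table)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(table)
  names(df)[names(df) == "activity"] <- "pchembl_value"
  for (fold in c("train", "test", "discarded")) {
    sub <- df[df$record_id %in% split[[fold]], , drop = FALSE]
    sub$fold <- rep(fold, nrow(sub))
    utils::write.csv(sub, file.path(dir, paste0(fold, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    n_records = nrow(table),
    n_train = length(split$train),
    n_test = length(split$test),
    n_discarded = length(split$discarded),
    achieved_test_fraction = safe_div(
      length(split$test), length(split$train) + length(split$test)),
    params = split$params
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
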