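# FeatureTable: the uniform id -> fixed-length numeric vector container
# used for both protein descriptors and compound fingerprints.

#' Create a feature table
#'
#' A feature table is a numeric matrix with one row per entity (row names
#' are the ids) and a `kind` attribute (`"protein"` or `"compound"`).
#' All values must be finite and every vector has the same length.
#'
#' @param x numeric matrix with row names, or a named list of equal-length
#'   numeric vectors.
#' @param kind `"protein"` or `"compound"`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(x, kind = c("protein", "compound")) {
  kind <- match.arg(kind)
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) > 1L) {
      abort("all feature vectors must have the same length")
    }
    x <- do.call(rbind, x)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || anyNA(rownames(x)) || any(rownames(x) == "")) {
    abort("feature table rows must be named by entity id")
  }
  if (anyDuplicated(rownames(x))) {
    abort("duplicate ids in feature table: %s",
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (any(!is.finite(x))) abort("feature table values must be finite")
  structure(x, kind = kind, class = c("feature_table", class(x)))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> kind=%s, %d ids x %d dimensions\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

ft_kind <- function(x) attr(x, "kind")

ft_ids <- function(x) rownames(x)

ft_dim <- function(x) ncol(x)

# subset rows of a feature table by id, preserving class/kind
ft_subset <- function(x, ids) {
  missing <- setdiff(ids, rownames(x))
  if (length(missing)) {
    abort("ids missing from feature table: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  feature_table(x[ids, , drop = FALSE], kind = ft_kind(x))
}

#' Read a delimited id + vector table
#'
#' First column is the entity id; all remaining columns must be numeric.
#' Comma- or tab-delimited with a header row (delimiter sniffed from the
#' first line unless given).
#'
#' @param path file path.
#' @param kind `"protein"` or `"compound"`.
#' @param sep delimiter; `NULL` to auto-detect.
#' @return a [feature_table()].
#' @export
read_vector_table <- function(path, kind = c("protein", "compound"),
                              sep = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort("file not found: %s", path)
  sep <- sep %||% sniff_sep(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) abort("malformed vector table %s: %s",
                              path, conditionMessage(e)))
  if (ncol(df) < 2L) abort("vector table needs an id column plus >= 1 numeric column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    abort("repeated id in vector table: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) abort("non-numeric feature values in %s", path)
  if (any(!is.finite(vals))) abort("non-finite feature values in %s", path)
  rownames(vals) <- ids
  feature_table(vals, kind = kind)
}

#' Write a feature table to a delimited file
#'
#' @param x a [feature_table()].
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_vector_table <- function(x, path) {
  df <- data.frame(id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# detect tab vs comma from the first line of a file
sniff_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) && grepl("\t", line)) "\t" else ","
}
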