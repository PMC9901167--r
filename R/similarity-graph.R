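# Binarized similarity edges and the heterogeneous protein/compound
# bioactivity network that drives the fully-dissimilar split.

#' Compound-compound similarity edges
#'
#' All-pairs Tanimoto over a binary fingerprint table; pairs at or above
#' the threshold become CC_SIM edges. The 0.5 threshold is the binarized
#' "similar compound" relation used by the dissimilar splits.
#'
#' @param fingerprints a [feature_table()] (kind `"compound"`) of binary
#'   fingerprints, or a 0/1 matrix with compound ids as rownames.
#' @param threshold inclusive Tanimoto threshold (default 0.5).
#' @return data frame with columns `from`, `to` (compound ids, from < to)
#'   and `similarity`.
#' @export
compound_similarity_edges <- function(fingerprints, threshold = 0.5) {
  fp <- as.matrix(fingerprints)
  if (nrow(fp) == 0L) {
    warning("empty fingerprint table: no similarity edges", call. = FALSE)
    return(data.frame(from = character(0), to = character(0),
                      similarity = numeric(0)))
  }
  if (!all(fp %in% c(0, 1))) abort("fingerprints must be binary")
  sim <- tanimoto_matrix(fp)
  idx <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
  data.frame(from = rownames(sim)[idx[, 1L]],
             to = rownames(sim)[idx[, 2L]],
             similarity = sim[idx],
             stringsAsFactors = FALSE)
}

#' Protein-protein similarity edges from a cluster map
#'
#' Proteins sharing a cluster are similar: each cluster contributes a
#' clique of PP_SIM edges (all unordered within-cluster pairs).
#'
#' @param clusters a [cluster_map()].
#' @return data frame with columns `from`, `to` (protein ids).
#' @export
protein_similarity_edges <- function(clusters) {
  if (!inherits(clusters, "cluster_map")) {
    abort("`clusters` must be a cluster_map")
  }
  prot <- names(clusters)
  out <- list()
  for (cl in unique(unclass(clusters))) {
    members <- sort(prot[unclass(clusters) == cl])
    if (length(members) < 2L) next
    pairs <- utils::combn(members, 2L)
    out[[cl]] <- data.frame(from = pairs[1L, ], to = pairs[2L, ],
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(from = character(0), to = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Similarity edges from a precomputed similarity matrix
#'
#' For externally computed protein-protein similarities (e.g. pairwise
#' alignment percent identities), pairs at or above `threshold` become
#' edges.
#'
#' @param sim numeric matrix with identical row/column ids.
#' @param threshold inclusive similarity threshold.
#' @return data frame with columns `from`, `to`, `similarity`.
#' @export
similarity_matrix_edges <- function(sim, threshold) {
  sim <- as.matrix(sim)
  if (is.null(rownames(sim)) || !identical(rownames(sim), colnames(sim))) {
    abort("similarity matrix must have matching row and column ids")
  }
  idx <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
  data.frame(from = rownames(sim)[idx[, 1L]],
             to = colnames(sim)[idx[, 2L]],
             similarity = sim[idx],
             stringsAsFactors = FALSE)
}

# internal node naming: compounds and proteins live in one igraph, so
# ids are prefixed by node kind
cnode <- function(id) paste0("c|", id)
pnode <- function(id) paste0("p|", id)
node_id <- function(name) sub("^[cp]\\|", "", name)
node_kind <- function(name) ifelse(startsWith(name, "c|"), "compound", "protein")

#' Build the heterogeneous bioactivity network
#'
#' Nodes are the distinct compounds and proteins of a bioactivity table;
#' edges are typed: `CC_SIM` (compound-compound similarity), `PP_SIM`
#' (protein-protein similarity) and `BIOACTIVITY` (one edge per record,
#' carrying its record id). Two network components that are disconnected
#' share no similarity at all, directly or indirectly, which is what the
#' fully-dissimilar split exploits.
#'
#' @param table a [bioactivity_table()].
#' @param cc_edges compound similarity edges (`from`, `to` columns), as
#'   from [compound_similarity_edges()].
#' @param pp_edges protein similarity edges, as from
#'   [protein_similarity_edges()].
#' @return An object of class `hetero_graph` wrapping an igraph graph.
#' @export
build_hetero_graph <- function(table, cc_edges = NULL, pp_edges = NULL) {
  assert_bioactivity_table(table)
  compounds <- unique(table$compound_id)
  proteins <- unique(table$protein_id)
  check_endpoints <- function(edges, universe, what) {
    if (is.null(edges) || nrow(edges) == 0L) {
      return(data.frame(from = character(0), to = character(0)))
    }
    unknown <- setdiff(unique(c(edges$from, edges$to)), universe)
    if (length(unknown)) {
      abort("%s edge endpoint(s) not present in the bioactivity table: %s",
            what, paste(utils::head(unknown, 5L), collapse = ", "))
    }
    edges[, c("from", "to"), drop = FALSE]
  }
  cc <- check_endpoints(cc_edges, compounds, "compound similarity")
  pp <- check_endpoints(pp_edges, proteins, "protein similarity")
  if (any(cc$from == cc$to) || any(pp$from == pp$to)) {
    abort("self-loop similarity edges are not allowed")
  }
  edge_df <- rbind(
    data.frame(from = cnode(table$compound_id), to = pnode(table$protein_id),
               kind = "BIOACTIVITY", record_id = table$record_id,
               stringsAsFactors = FALSE),
    if (nrow(cc)) data.frame(from = cnode(cc$from), to = cnode(cc$to),
                             kind = "CC_SIM", record_id = NA_integer_,
                             stringsAsFactors = FALSE),
    if (nrow(pp)) data.frame(from = pnode(pp$from), to = pnode(pp$to),
                             kind = "PP_SIM", record_id = NA_integer_,
                             stringsAsFactors = FALSE)
  )
  vertices <- data.frame(
    name = c(cnode(compounds), pnode(proteins)),
    kind = c(rep("compound", length(compounds)),
             rep("protein", length(proteins))),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                     vertices = vertices)
  structure(list(graph = g, table = table), class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  g <- x$graph
  kinds <- igraph::E(g)$kind
  cat(sprintf(
    "<hetero_graph> %d compounds, %d proteins; edges: %d bioactivity, %d CC_SIM, %d PP_SIM\n",
    sum(igraph::V(g)$kind == "compound"),
    sum(igraph::V(g)$kind == "protein"),
    sum(kinds == "BIOACTIVITY"), sum(kinds == "CC_SIM"),
    sum(kinds == "PP_SIM")))
  invisible(x)
}
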