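# Train/test splitting strategies. Three difficulty levels:
#   random              - uniform record assignment (shared similar
#                         compounds and proteins across folds);
#   dissimilar-compound - whole compound-similarity components per fold,
#                         so no similar compound pair crosses folds;
#   fully-dissimilar    - network-based: components of the heterogeneous
#                         similarity/bioactivity graph are assigned whole,
#                         with Louvain community pruning of the giant
#                         component, so neither similar compounds nor
#                         same-cluster proteins cross folds.

new_split_result <- function(train, test, discarded, params) {
  structure(list(train = sort(as.integer(train)),
                 test = sort(as.integer(test)),
                 discarded = sort(as.integer(discarded)),
                 params = params),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  n <- length(x$train) + length(x$test) + length(x$discarded)
  cat(sprintf(
    "<split_result> strategy=%s: %d train / %d test / %d discarded (test fraction %.3f of retained)\n",
    x$params$strategy %||% "?", length(x$train), length(x$test),
    length(x$discarded),
    safe_div(length(x$test), length(x$train) + length(x$test))))
  invisible(x)
}

assert_split_result <- function(split, table) {
  if (!inherits(split, "split_result")) abort("expected a split_result")
  ids <- c(split$train, split$test, split$discarded)
  if (anyDuplicated(ids)) {
    abort("train/test/discarded folds overlap on record id(s): %s",
          paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  }
  if (!setequal(ids, table$record_id)) {
    abort("split does not partition the table's record ids")
  }
  invisible(split)
}

# Component-to-fold assignment: exact subset-sum search for the set of
# whole components whose record count is closest to the target test
# size. Components are visited in a seeded shuffle (stably ordered
# largest-first), which resolves ties among equal-sized components
# deterministically for a given seed.
assign_components <- function(sizes, target_n, seed) {
  k <- length(sizes)
  ord <- with_seed(seed, sample.int(k))
  ord <- ord[order(-sizes[ord])]
  total <- sum(sizes)
  # reachable[s + 1]: sum s achievable; chose[s + 1]: index of the
  # component added last to reach s (0 = empty set)
  reachable <- c(TRUE, rep(FALSE, total))
  chose <- integer(total + 1L)
  for (i in ord) {
    si <- sizes[i]
    if (si == 0L) next
    can <- which(reachable)
    new <- can + si
    fresh <- new[!reachable[new]]
    reachable[fresh] <- TRUE
    chose[fresh] <- i
  }
  sums <- which(reachable) - 1L
  best <- sums[order(abs(sums - target_n), sums)][1L]
  in_test <- logical(k)
  s <- best
  while (s > 0L) {
    i <- chose[s + 1L]
    in_test[i] <- TRUE
    s <- s - sizes[i]
  }
  in_test
}

#' Random split
#'
#' Seeded uniform assignment of records to train/test. The easiest
#' benchmark setting: similar compounds and proteins freely cross folds.
#'
#' @param table a [bioactivity_table()].
#' @param test_fraction fraction of records in the test fold (0 < f < 1).
#' @param seed integer seed.
#' @return a `split_result` (discarded is empty).
#' @export
split_random <- function(table, test_fraction, seed = 1L) {
  assert_bioactivity_table(table)
  n <- nrow(table)
  if (n < 2L) abort("need at least 2 records to split")
  if (!is_prob(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be strictly between 0 and 1")
  }
  n_test <- max(1L, min(n - 1L, round(test_fraction * n)))
  test <- with_seed(seed, sample(table$record_id, n_test))
  new_split_result(setdiff(table$record_id, test), test, integer(0),
                   list(strategy = "random", test_fraction = test_fraction,
                        seed = seed))
}

#' Dissimilar-compound split
#'
#' Connected components of the compound-similarity graph (edges =
#' Tanimoto >= threshold pairs) are assigned whole to train or test, so no
#' similar compound pair crosses folds; proteins may appear in both folds.
#'
#' @param table a [bioactivity_table()].
#' @param cc_edges compound similarity edges from
#'   [compound_similarity_edges()] (built at the binarization threshold,
#'   0.5 by default).
#' @param test_fraction target fraction of records in the test fold.
#' @param seed integer seed.
#' @return a `split_result` (discarded is empty).
#' @export
split_dissimilar_compound <- function(table, cc_edges, test_fraction,
                                      seed = 1L) {
  assert_bioactivity_table(table)
  if (!is_prob(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be strictly between 0 and 1")
  }
  compounds <- unique(table$compound_id)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(compounds)
  if (!is.null(cc_edges) && nrow(cc_edges) > 0L) {
    unknown <- setdiff(unique(c(cc_edges$from, cc_edges$to)), compounds)
    if (length(unknown)) {
      abort("similarity edge endpoint(s) not in the table: %s",
            paste(utils::head(unknown, 5L), collapse = ", "))
    }
    g <- igraph::add_edges(g, rbind(cc_edges$from, cc_edges$to))
  }
  memb <- igraph::components(g)$membership
  comp_of_record <- memb[table$compound_id]
  sizes <- as.integer(table(factor(comp_of_record,
                                   levels = seq_len(max(memb)))))
  target_n <- round(test_fraction * nrow(table))
  in_test <- assign_components(sizes, target_n, seed)
  test <- table$record_id[in_test[comp_of_record]]
  train <- setdiff(table$record_id, test)
  if (length(test) == 0L || length(train) == 0L) {
    abort(paste0("infeasible dissimilar-compound split: a single compound ",
                 "component covers all records"))
  }
  new_split_result(train, test, integer(0),
                   list(strategy = "dissimilar_compound",
                        test_fraction = test_fraction, seed = seed))
}

#' Fully-dissimilar (network-based) split
#'
#' Splits bioactivity records into disconnected components of the
#' heterogeneous network so that no similar compound pair and no
#' same-cluster protein pair crosses folds. Protein clusters (PP_SIM
#' cliques) are contracted to super-nodes before community detection, so
#' a cluster can never span folds. While no whole-component assignment
#' can reach the target test fraction (within `tolerance`), the largest
#' component is subdivided: Louvain communities are detected (seeded),
#' bioactivity edges crossing communities are discarded, and for
#' compound-similarity edges crossing communities the endpoint compound
#' with fewer bioactivity records (ties: lexicographically smaller id) is
#' removed together with its records. Up to `max_rounds` pruning rounds
#' are attempted.
#'
#' @param graph a [build_hetero_graph()] network.
#' @param test_fraction target test fraction of the retained records.
#' @param tolerance acceptable deviation of the achieved test fraction
#'   (default 0.05).
#' @param louvain_resolution Louvain resolution parameter (default 1.0).
#' @param max_rounds cap on pruning rounds (default 10).
#' @param seed integer seed (component shuffle and Louvain).
#' @return a `split_result`; `discarded` holds the records removed on
#'   pruned edges/nodes.
#' @export
split_fully_dissimilar <- function(graph, test_fraction,
                                   tolerance = 0.05,
                                   louvain_resolution = 1.0,
                                   max_rounds = 10L, seed = 1L) {
  if (!inherits(graph, "hetero_graph")) {
    abort("`graph` must be a hetero_graph (see build_hetero_graph())")
  }
  if (!is_prob(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be strictly between 0 and 1")
  }
  table <- graph$table
  g <- graph$graph
  enames <- igraph::as_edgelist(g, names = TRUE)
  ekind <- igraph::E(g)$kind

  # contract protein clusters: connected components of the PP_SIM subgraph
  pp <- enames[ekind == "PP_SIM", , drop = FALSE]
  prot_nodes <- igraph::V(g)$name[igraph::V(g)$kind == "protein"]
  pg <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(prot_nodes)
  if (nrow(pp)) pg <- igraph::add_edges(pg, t(pp))
  pmemb <- igraph::components(pg)$membership
  super_of <- stats::setNames(paste0("S", pmemb), names(pmemb))

  # live state: bioactivity records (compound node, protein super-node)
  # and compound-compound similarity edges
  records <- data.frame(
    record_id = table$record_id,
    compound = cnode(table$compound_id),
    super = unname(super_of[pnode(table$protein_id)]),
    stringsAsFactors = FALSE
  )
  cc <- enames[ekind == "CC_SIM", , drop = FALSE]
  cc <- data.frame(from = cc[, 1L], to = cc[, 2L], stringsAsFactors = FALSE)
  discarded <- integer(0)

  build_working_graph <- function(records, cc) {
    nodes <- unique(c(records$compound, records$super, cc$from, cc$to))
    wg <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(nodes)
    edges <- rbind(unique(records[, c("compound", "super")]),
                   stats::setNames(cc, c("compound", "super")))
    if (nrow(edges)) {
      wg <- igraph::add_edges(wg, rbind(edges$compound, edges$super))
    }
    wg
  }

  achieved_history <- numeric(0)
  for (round in 0:max_rounds) {
    wg <- build_working_graph(records, cc)
    memb <- igraph::components(wg)$membership
    comp_of_record <- memb[records$compound]
    n_live <- nrow(records)
    if (n_live == 0L) {
      abort(paste0("fully-dissimilar split infeasible: every record was ",
                   "discarded during pruning"))
    }
    sizes <- as.integer(table(factor(comp_of_record,
                                     levels = seq_len(max(memb)))))
    target_n <- round(test_fraction * n_live)
    in_test <- assign_components(sizes, target_n, seed)
    test <- records$record_id[in_test[comp_of_record]]
    achieved <- safe_div(length(test), n_live)
    achieved_history <- c(achieved_history, achieved)
    feasible <- length(test) > 0L && length(test) < n_live &&
      abs(achieved - test_fraction) <= tolerance
    if (feasible) {
      train <- setdiff(records$record_id, test)
      return(new_split_result(
        train, test, discarded,
        list(strategy = "fully_dissimilar", test_fraction = test_fraction,
             tolerance = tolerance, louvain_resolution = louvain_resolution,
             rounds_used = round, seed = seed)))
    }
    if (round == max_rounds) break

    # prune the largest component (by record count) via Louvain; if the
    # requested resolution leaves the component whole, escalate it until
    # the component subdivides (coarse partitions cut fewer edges, so the
    # lowest workable resolution minimizes data loss)
    big <- which.max(sizes)
    big_nodes <- names(memb)[memb == big]
    sub <- igraph::induced_subgraph(wg, big_nodes)
    res_round <- louvain_resolution
    for (try in 1:12) {
      comm <- with_seed(seed + 1009L * (round + 1L) + try, igraph::membership(
        igraph::cluster_louvain(sub, resolution = res_round)))
      if (max(comm) > 1L) break
      res_round <- res_round * 1.5
    }
    if (max(comm) == 1L) {
      abort(paste0("fully-dissimilar split infeasible: the giant component ",
                   "cannot be subdivided by community detection"))
    }
    # bioactivity edges whose endpoints fall in different communities
    in_big <- records$compound %in% big_nodes
    cross_rec <- in_big &
      comm[records$compound] != comm[records$super]
    discarded <- c(discarded, records$record_id[cross_rec])
    records <- records[!cross_rec, , drop = FALSE]
    # compound-similarity edges crossing communities: drop the endpoint
    # compound with fewer live records (ties: lexicographically smaller)
    cc_in_big <- cc$from %in% big_nodes & cc$to %in% big_nodes
    cross_cc <- cc_in_big & comm[cc$from] != comm[cc$to]
    if (any(cross_cc)) {
      drop_nodes <- character(0)
      for (i in which(cross_cc)) {
        a <- cc$from[i]
        b <- cc$to[i]
        if (a %in% drop_nodes || b %in% drop_nodes) next
        na <- sum(records$compound == a)
        nb <- sum(records$compound == b)
        victim <- if (na < nb) a else if (nb < na) b else min(a, b)
        drop_nodes <- c(drop_nodes, victim)
      }
      drop_rec <- records$compound %in% drop_nodes
      discarded <- c(discarded, records$record_id[drop_rec])
      records <- records[!drop_rec, , drop = FALSE]
      cc <- cc[!(cc$from %in% drop_nodes | cc$to %in% drop_nodes), ,
               drop = FALSE]
    }
  }
  abort(paste0(
    "fully-dissimilar split infeasible: test fraction %.3f (+/- %.3f) not ",
    "reachable after %d pruning round(s); achievable fractions were %s"),
    test_fraction, tolerance, max_rounds,
    paste(sprintf("%.3f", achieved_history), collapse = ", "))
}

#' Harmonize companion splits with a reference split
#'
#' Records discarded by the reference split (typically the
#' fully-dissimilar one) are moved to the discarded fold of every other
#' split, so that all strategies operate on exactly the same record
#' universe and their results are directly comparable.
#'
#' @param reference a `split_result`.
#' @param others list of `split_result`s over the same record universe.
#' @return list of harmonized `split_result`s.
#' @export
harmonize_splits <- function(reference, others) {
  if (!inherits(reference, "split_result")) abort("expected split_result")
  universe <- sort(c(reference$train, reference$test, reference$discarded))
  lapply(others, function(s) {
    if (!inherits(s, "split_result")) abort("expected split_result")
    s_universe <- sort(c(s$train, s$test, s$discarded))
    if (!identical(universe, s_universe)) {
      abort("splits cover different record universes")
    }
    drop <- reference$discarded
    new_split_result(setdiff(s$train, drop), setdiff(s$test, drop),
                     union(s$discarded, drop),
                     c(s$params, list(harmonized_with = reference$params$strategy)))
  })
}
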