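# Synthetic benchmark generator. Emulates the statistical structure of
# curated bioactivity datasets: compound families with controlled
# within/between Tanimoto similarity, protein clusters with controlled
# sequence divergence, and bioactivities composed of family, cluster and
# family-by-cluster interaction effects with Gaussian noise and optional
# assay-floor censoring (values below the floor recorded exactly at the
# floor, as in Davis-style Kd panels).

#' Synthetic benchmark configuration
#'
#' Defaults describe a desk-scale benchmark with clearly separated
#' compound families (within-family Tanimoto well above the 0.5
#' similarity threshold, between-family well below), protein clusters
#' diverged by point substitutions, and activities around a typical
#' bioactivity median with family/cluster/interaction structure.
#'
#' @param n_compound_families number of compound families.
#' @param compounds_per_family compounds per family.
#' @param fingerprint_bits fingerprint width.
#' @param template_density probability of a set bit in a family template.
#' @param bit_flip_prob per-bit flip probability for family members.
#' @param n_protein_clusters number of protein clusters.
#' @param proteins_per_cluster proteins per cluster.
#' @param seq_length protein sequence length (residues).
#' @param mutation_rate per-residue substitution probability within a
#'   cluster.
#' @param activity_base baseline pChEMBL value.
#' @param family_effect_sd,cluster_effect_sd,interaction_sd standard
#'   deviations (pChEMBL units) of the per-family, per-cluster and
#'   per-(family, cluster) Gaussian effects.
#' @param noise_sd measurement noise standard deviation (pChEMBL units).
#' @param censor_floor assay floor: latent activities below it are
#'   recorded exactly at this value (`NULL` disables censoring).
#' @param density fraction of (compound, protein) pairs measured (within
#'   screened panels when `screen_block_prob < 1`).
#' @param screen_block_prob probability that a (compound family, protein
#'   cluster) panel is screened at all. The default 1 measures a uniform
#'   random subset of all pairs; values below 1 emulate the panel
#'   structure of target-based assay campaigns, where a compound series
#'   is screened against a subset of target groups and the bioactivity
#'   network is correspondingly modular.
#' @param seed integer seed.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compound_families = 12L,
                             compounds_per_family = 8L,
                             fingerprint_bits = 1024L,
                             template_density = 0.1,
                             bit_flip_prob = 0.01,
                             n_protein_clusters = 8L,
                             proteins_per_cluster = 4L,
                             seq_length = 120L,
                             mutation_rate = 0.05,
                             activity_base = 6.5,
                             family_effect_sd = 0.8,
                             cluster_effect_sd = 0.6,
                             interaction_sd = 0.5,
                             noise_sd = 0.3,
                             censor_floor = 5.0,
                             density = 0.25,
                             screen_block_prob = 1.0,
                             seed = 1L) {
  cfg <- list(n_compound_families = n_compound_families,
              compounds_per_family = compounds_per_family,
              fingerprint_bits = fingerprint_bits,
              template_density = template_density,
              bit_flip_prob = bit_flip_prob,
              n_protein_clusters = n_protein_clusters,
              proteins_per_cluster = proteins_per_cluster,
              seq_length = seq_length,
              mutation_rate = mutation_rate,
              activity_base = activity_base,
              family_effect_sd = family_effect_sd,
              cluster_effect_sd = cluster_effect_sd,
              interaction_sd = interaction_sd,
              noise_sd = noise_sd,
              censor_floor = censor_floor,
              density = density,
              screen_block_prob = screen_block_prob,
              seed = seed)
  for (f in c("n_compound_families", "compounds_per_family",
              "fingerprint_bits", "n_protein_clusters",
              "proteins_per_cluster", "seq_length")) {
    if (!is_count(cfg[[f]])) abort("`%s` must be a positive integer", f)
  }
  for (f in c("template_density", "bit_flip_prob", "mutation_rate",
              "density", "screen_block_prob")) {
    if (!is_prob(cfg[[f]])) abort("`%s` must be a probability in [0, 1]", f)
  }
  for (f in c("family_effect_sd", "cluster_effect_sd", "interaction_sd",
              "noise_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      abort("`%s` must be a non-negative number", f)
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate synthetic compounds
#'
#' Each family has a random template fingerprint (bits set independently
#' with `template_density`); members are copies of the template with
#' independent per-bit flips at `bit_flip_prob`. Deterministic given the
#' config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `fingerprints` (a compound [feature_table()]) and
#'   `families` (named character vector compound id -> family id).
#' @export
gen_compounds <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 1L, {
    nf <- cfg$n_compound_families
    mpf <- cfg$compounds_per_family
    w <- cfg$fingerprint_bits
    rows <- list()
    families <- character(0)
    for (f in seq_len(nf)) {
      template <- stats::rbinom(w, 1L, cfg$template_density)
      for (m in seq_len(mpf)) {
        flips <- stats::rbinom(w, 1L, cfg$bit_flip_prob)
        id <- sprintf("cmp%03d_%02d", f, m)
        rows[[id]] <- as.numeric(xor(template, flips))
        families[id] <- sprintf("fam%02d", f)
      }
    }
    fp <- do.call(rbind, rows)
    rownames(fp) <- names(rows)
    list(fingerprints = feature_table(fp, kind = "compound"),
         families = families)
  })
}

#' Generate synthetic proteins
#'
#' Each cluster has a random ancestor sequence; members carry independent
#' point substitutions at `mutation_rate` (substituted residues are drawn
#' from the 19 alternatives). Deterministic given the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `sequences` (named character vector) and `clusters`
#'   (a [cluster_map()]).
#' @export
gen_proteins <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 2L, {
    seqs <- character(0)
    clusters <- character(0)
    for (cl in seq_len(cfg$n_protein_clusters)) {
      ancestor <- sample(AA20, cfg$seq_length, replace = TRUE)
      for (m in seq_len(cfg$proteins_per_cluster)) {
        res <- ancestor
        mut <- which(stats::runif(cfg$seq_length) < cfg$mutation_rate)
        for (i in mut) {
          res[i] <- sample(setdiff(AA20, res[i]), 1L)
        }
        id <- sprintf("prot%02d_%02d", cl, m)
        seqs[id] <- paste(res, collapse = "")
        clusters[id] <- sprintf("clu%02d", cl)
      }
    }
    list(sequences = seqs, clusters = cluster_map(clusters))
  })
}

#' Generate synthetic bioactivities
#'
#' For a seeded random subset of (compound, protein) pairs (fraction
#' `density`), the latent activity is
#' `activity_base + family effect + cluster effect +
#' (family, cluster) interaction + Gaussian noise`, with effects drawn
#' once per level from centered Gaussians of the configured standard
#' deviations. If `censor_floor` is set, latent values below it are
#' recorded exactly at the floor.
#'
#' @param compounds output of [gen_compounds()].
#' @param proteins output of [gen_proteins()].
#' @param cfg a [synthetic_config()].
#' @return a [bioactivity_table()]; the drawn effects are attached as
#'   attribute `"effects"` (ground truth for diagnostics and tests).
#' @export
gen_bioactivities <- function(compounds, proteins, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  families <- compounds$families
  clusters <- proteins$clusters
  with_seed(cfg$seed + 3L, {
    fam_levels <- sort(unique(unname(families)))
    clu_levels <- sort(unique(unclass(clusters)))
    fam_eff <- stats::setNames(
      stats::rnorm(length(fam_levels), 0, cfg$family_effect_sd), fam_levels)
    clu_eff <- stats::setNames(
      stats::rnorm(length(clu_levels), 0, cfg$cluster_effect_sd), clu_levels)
    inter_eff <- matrix(
      stats::rnorm(length(fam_levels) * length(clu_levels), 0,
                   cfg$interaction_sd),
      nrow = length(fam_levels),
      dimnames = list(fam_levels, clu_levels))
    grid <- expand.grid(compound_id = names(families),
                        protein_id = names(clusters),
                        stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < cfg$density
    if (cfg$screen_block_prob < 1) {
      screened <- matrix(
        stats::runif(length(fam_levels) * length(clu_levels)) <
          cfg$screen_block_prob,
        nrow = length(fam_levels),
        dimnames = list(fam_levels, clu_levels))
      keep <- keep & screened[cbind(families[grid$compound_id],
                                    unclass(clusters)[grid$protein_id])]
    }
    if (!any(keep)) {
      warning("density produced an empty bioactivity table", call. = FALSE)
    }
    grid <- grid[keep, , drop = FALSE]
    fam <- families[grid$compound_id]
    clu <- unclass(clusters)[grid$protein_id]
    latent <- cfg$activity_base + fam_eff[fam] + clu_eff[clu] +
      inter_eff[cbind(fam, clu)] +
      stats::rnorm(nrow(grid), 0, cfg$noise_sd)
    recorded <- latent
    if (!is.null(cfg$censor_floor)) {
      recorded[recorded < cfg$censor_floor] <- cfg$censor_floor
    }
    out <- bioactivity_table(grid$compound_id, grid$protein_id, recorded)
    attr(out, "effects") <- list(family = fam_eff, cluster = clu_eff,
                                 interaction = inter_eff)
    out
  })
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper: compounds, proteins and bioactivities from one
#' config.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `compounds`, `proteins`, `table`.
#' @export
gen_benchmark <- function(cfg = synthetic_config()) {
  compounds <- gen_compounds(cfg)
  proteins <- gen_proteins(cfg)
  table <- gen_bioactivities(compounds, proteins, cfg)
  list(compounds = compounds, proteins = proteins, table = table,
       config = cfg)
}
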