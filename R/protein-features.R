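# Protein sequence descriptors computed natively: dde (dipeptide deviation
# from expected mean), taap (total amino acid properties), spmap
# (subsequence profile map over BLOSUM62 k-mer clusters), and the
# random200 baseline. Descriptors that require external profile databases
# (PSSM, Pfam domains, learned embeddings) enter via read_vector_table().

# Sense-codon counts of the standard genetic code (61 coding codons),
# used for the theoretical dipeptide mean in dde.
CODON_COUNTS <- c(A = 4, R = 6, N = 2, D = 2, C = 2, Q = 2, E = 2, G = 4,
                  H = 2, I = 3, L = 6, K = 2, M = 1, F = 2, P = 4, S = 6,
                  T = 4, W = 1, Y = 2, V = 4)

#' The ten AAindex property scales of the taap descriptor
#'
#' Named list of ten numeric vectors (one value per canonical residue),
#' named by AAindex accession: CIDH920105 normalized average
#' hydrophobicity scale; BHAR880101 average flexibility indices;
#' CHAM820101 polarizability parameter; CHAM820102 free energy of
#' solution in water; CHOC760101 residue accessible surface area in
#' tripeptide; BIGC670101 residue volume; CHAM810101 steric parameter;
#' DAYM780201 relative mutability; HOPT810101 hydrophilicity value;
#' KRIW790103 side chain volume.
#'
#' @export
TAAP_PROPERTIES <- list(
  CIDH920105 = c(A = 0.02, R = -0.42, N = -0.77, D = -1.04, C = 0.77, Q = -1.10, E = -1.14, G = -0.80, H = 0.26, I = 1.81, L = 1.14, K = -0.41, M = 1.00, F = 1.35, P = -0.09, S = -0.97, T = -0.77, W = 1.71, Y = 1.11, V = 1.13),
  BHAR880101 = c(A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346, Q = 0.493, E = 0.497, G = 0.544, H = 0.323, I = 0.462, L = 0.365, K = 0.466, M = 0.295, F = 0.314, P = 0.509, S = 0.507, T = 0.444, W = 0.305, Y = 0.420, V = 0.386),
  CHAM820101 = c(A = 0.046, R = 0.291, N = 0.134, D = 0.105, C = 0.128, Q = 0.180, E = 0.151, G = 0.000, H = 0.230, I = 0.186, L = 0.186, K = 0.219, M = 0.221, F = 0.290, P = 0.131, S = 0.062, T = 0.108, W = 0.409, Y = 0.298, V = 0.140),
  CHAM820102 = c(A = -0.368, R = -1.03, N = 0.0, D = 2.06, C = 4.53, Q = 0.731, E = 1.77, G = -0.525, H = 0.0, I = 0.791, L = 1.07, K = 0.0, M = 0.656, F = 1.06, P = -2.24, S = -0.524, T = 0.0, W = 1.60, Y = 4.91, V = 0.401),
  CHOC760101 = c(A = 115, R = 225, N = 160, D = 150, C = 135, Q = 180, E = 190, G = 75, H = 195, I = 175, L = 170, K = 200, M = 185, F = 210, P = 145, S = 115, T = 140, W = 255, Y = 230, V = 155),
  BIGC670101 = c(A = 52.6, R = 109.1, N = 75.7, D = 68.4, C = 68.3, Q = 89.7, E = 84.7, G = 36.3, H = 91.9, I = 102.0, L = 102.0, K = 105.1, M = 97.7, F = 113.9, P = 73.6, S = 54.9, T = 71.2, W = 135.4, Y = 116.2, V = 85.1),
  CHAM810101 = c(A = 0.52, R = 0.68, N = 0.76, D = 0.76, C = 0.62, Q = 0.68, E = 0.68, G = 0.00, H = 0.70, I = 1.02, L = 0.98, K = 0.68, M = 0.78, F = 0.70, P = 0.36, S = 0.53, T = 0.50, W = 0.70, Y = 0.70, V = 0.76),
  DAYM780201 = c(A = 100, R = 65, N = 134, D = 106, C = 20, Q = 93, E = 102, G = 49, H = 66, I = 96, L = 40, K = 56, M = 94, F = 41, P = 56, S = 120, T = 97, W = 18, Y = 41, V = 74),
  HOPT810101 = c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0, G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
  KRIW790103 = c(A = 27.5, R = 105.0, N = 58.7, D = 40.0, C = 44.6, Q = 80.7, E = 62.0, G = 0.0, H = 79.0, I = 93.5, L = 93.5, K = 100.0, M = 94.1, F = 115.5, P = 41.9, S = 29.3, T = 51.3, W = 145.5, Y = 117.3, V = 71.5)
)

check_sequence <- function(sequence, min_len = 1L) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("`sequence` must be a single string")
  }
  if (nchar(sequence) < min_len) {
    abort("sequence must have length >= %d", min_len)
  }
  res <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(res), AA20)
  if (length(bad)) {
    abort("non-canonical residues in sequence: %s", paste(bad, collapse = ", "))
  }
  res
}

# the 400 dipeptides in lexicographic order AA, AC, ..., YY
dipeptide_order <- function() {
  as.vector(t(outer(AA20_SORTED, AA20_SORTED, paste0)))
}

#' Dipeptide deviation from expected mean (dde)
#'
#' For each of the 400 dipeptides the descriptor is
#' `(Dc - Tm) / sqrt(Tv)` where `Dc` is the observed dipeptide fraction,
#' `Tm = (Ca/61) * (Cb/61)` is the theoretical mean from standard genetic
#' code codon counts, and `Tv = Tm * (1 - Tm) / (N - 1)` its theoretical
#' variance for a sequence with `N - 1` dipeptides.
#'
#' @param sequence a protein sequence (canonical residues, length >= 2).
#' @return named numeric vector of length 400, dipeptides ordered
#'   lexicographically (AA .. YY).
#' @export
dde <- function(sequence) {
  res <- check_sequence(sequence, min_len = 2L)
  n_dip <- length(res) - 1L
  dips <- paste0(res[-length(res)], res[-1L])
  order <- dipeptide_order()
  dc <- as.numeric(table(factor(dips, levels = order))) / n_dip
  ca <- CODON_COUNTS[substr(order, 1L, 1L)] / 61
  cb <- CODON_COUNTS[substr(order, 2L, 2L)] / 61
  tm <- as.numeric(ca * cb)
  tv <- tm * (1 - tm) / n_dip
  out <- (dc - tm) / sqrt(tv)
  names(out) <- order
  out
}

#' Total amino acid properties (taap)
#'
#' Sum over residues of ten physicochemical AAindex scales (hydrophobicity,
#' flexibility, polarizability, solution free energy, accessible surface
#' area, residue volume, steric parameter, relative mutability,
#' hydrophilicity, side-chain volume). The AAindex accessions are listed
#' with [TAAP_PROPERTIES].
#'
#' @param sequence a protein sequence (canonical residues).
#' @param properties list of named per-residue scales; each must cover all
#'   20 canonical residues. Defaults to the packaged ten scales.
#' @return named numeric vector, one total per property.
#' @export
taap <- function(sequence, properties = TAAP_PROPERTIES) {
  res <- check_sequence(sequence, min_len = 1L)
  vapply(properties, function(scale) {
    if (!all(AA20 %in% names(scale))) {
      abort("a property scale does not cover all 20 canonical residues")
    }
    sum(scale[res])
  }, numeric(1))
}

blosum62_matrix <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  data_env$BLOSUM62[AA20, AA20]
}

# ungapped position-wise BLOSUM62 score between equal-length k-mers
kmer_score <- function(a, b, mat) {
  sa <- strsplit(a, "")[[1L]]
  sb <- strsplit(b, "")[[1L]]
  sum(mat[cbind(sa, sb)])
}

extract_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  vapply(seq_len(n - k + 1L), function(i) substr(sequence, i, i + k - 1L),
         character(1))
}

#' Fit a subsequence profile map (spmap) model
#'
#' Extracts all k-mers (sliding window) from the input sequences and
#' greedily clusters them by ungapped BLOSUM62 similarity: k-mers are
#' visited in decreasing frequency order (ties broken lexicographically);
#' a k-mer whose best score against every existing cluster center is
#' below `score_threshold` founds a new center, until `max_centers`
#' centers exist.
#'
#' @param sequences character vector of protein sequences.
#' @param k subsequence length (default 5).
#' @param score_threshold minimum BLOSUM62 score for a k-mer to be
#'   absorbed by an existing center (default 15).
#' @param max_centers cap on the number of centers (default 512).
#' @return An object of class `spmap_model` with fields `k`, `centers`,
#'   `score_threshold`.
#' @export
spmap_fit <- function(sequences, k = 5L, score_threshold = 15,
                      max_centers = 512L) {
  if (!is_count(k)) abort("`k` must be a positive integer")
  if (!is_count(max_centers)) abort("`max_centers` must be a positive integer")
  kmers <- unlist(lapply(sequences, extract_kmers, k = k))
  if (length(kmers) == 0L) {
    abort("no k-mer of length %d extractable from the input sequences", k)
  }
  counts <- table(kmers)
  ord <- names(counts)[order(-as.numeric(counts), names(counts))]
  mat <- blosum62_matrix()
  centers <- character(0)
  for (km in ord) {
    if (length(centers) >= max_centers) break
    if (length(centers) == 0L) {
      centers <- km
      next
    }
    best <- max(vapply(centers, kmer_score, numeric(1), b = km, mat = mat))
    if (best < score_threshold) centers <- c(centers, km)
  }
  structure(list(k = as.integer(k), centers = centers,
                 score_threshold = score_threshold),
            class = "spmap_model")
}

#' @export
print.spmap_model <- function(x, ...) {
  cat(sprintf("<spmap_model> k=%d, %d centers, score threshold %s\n",
              x$k, length(x$centers), format(x$score_threshold)))
  invisible(x)
}

#' Transform a sequence with an spmap model
#'
#' Every k-mer of the sequence is assigned to its best-scoring center
#' (ties to the lexicographically smallest center); the feature vector is
#' the per-center assignment count divided by the total k-mer count, so
#' entries sum to 1.
#'
#' @param model an [spmap_fit()] model.
#' @param sequence protein sequence of length >= `model$k`.
#' @return numeric vector of length `length(model$centers)`, named by
#'   center.
#' @export
spmap_transform <- function(model, sequence) {
  if (!inherits(model, "spmap_model")) abort("`model` must be an spmap_model")
  kmers <- extract_kmers(sequence, model$k)
  if (length(kmers) == 0L) {
    abort("sequence shorter than k = %d", model$k)
  }
  mat <- blosum62_matrix()
  centers <- model$centers
  counts <- stats::setNames(numeric(length(centers)), centers)
  for (km in unique(kmers)) {
    scores <- vapply(centers, kmer_score, numeric(1), b = km, mat = mat)
    best <- which(scores == max(scores))
    # ties: lexicographically smallest center
    pick <- best[order(centers[best])][1L]
    counts[pick] <- counts[pick] + sum(kmers == km)
  }
  counts / length(kmers)
}

#' Random continuous protein baseline vectors (random200)
#'
#' 200 i.i.d. Uniform(0, 1) values per protein, used as the
#' protein-side baseline representation.
#'
#' @param n number of vectors.
#' @param dim vector length (default 200).
#' @param seed integer seed.
#' @return numeric matrix `n x dim` with rownames `rnd_prot<k>`.
#' @export
random200 <- function(n = 1L, dim = 200L, seed = 1L) {
  if (!is_count(n) || !is_count(dim)) abort("`n` and `dim` must be counts")
  m <- with_seed(seed, matrix(stats::runif(n * dim), nrow = n, ncol = dim))
  rownames(m) <- sprintf("rnd_prot%d", seq_len(n))
  m
}

#' Compute a protein feature table for a set of sequences
#'
#' @param sequences named character vector of sequences (names are
#'   protein ids).
#' @param method one of `"dde"`, `"taap"`, `"spmap"`, `"random200"`.
#' @param spmap_model required when `method = "spmap"`.
#' @param seed seed for `"random200"`.
#' @return a [feature_table()] of kind `"protein"`.
#' @export
protein_feature_table <- function(sequences,
                                  method = c("dde", "taap", "spmap",
                                             "random200"),
                                  spmap_model = NULL, seed = 1L) {
  method <- match.arg(method)
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    abort("`sequences` must be named by protein id")
  }
  vecs <- switch(method,
    dde = lapply(sequences, dde),
    taap = lapply(sequences, taap),
    spmap = {
      if (is.null(spmap_model)) spmap_model <- spmap_fit(sequences)
      lapply(sequences, spmap_transform, model = spmap_model)
    },
    random200 = {
      m <- random200(length(sequences), seed = seed)
      rownames(m) <- names(sequences)
      return(feature_table(m, kind = "protein"))
    })
  m <- do.call(rbind, vecs)
  rownames(m) <- names(sequences)
  feature_table(m, kind = "protein")
}
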