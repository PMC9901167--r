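# Compound featurization: ECFP4 circular fingerprints (via Open Babel
# through ChemmineOB), Tanimoto similarity, and random baseline
# fingerprints used by the dummy models.

#' ECFP4 fingerprint of a SMILES string
#'
#' Hashed extended-connectivity fingerprint of radius 2 (diameter 4),
#' folded to `width` bits. Bit assignment follows the Open Babel ECFP
#' implementation; its native 4096-bit vector is folded by OR-ing bit
#' `i` with bits `i + k*width`. Tanimoto-based thresholds are stable
#' under any consistent hashed mapping.
#'
#' @param smiles character vector of SMILES strings.
#' @param width fingerprint width in bits (default 1024).
#' @return a 0/1 matrix with one row per input (rownames = names of
#'   `smiles` if set, else the SMILES themselves).
#' @export
ecfp4 <- function(smiles, width = 1024L) {
  if (!is_count(width)) abort("`width` must be a positive integer")
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("ECFP4 computation requires the ChemmineOB package")
  }
  raw <- lapply(smiles, function(s) {
    mol <- tryCatch(
      suppressWarnings(ChemmineOB::forEachMol("SMILES", s, identity)),
      error = function(e) NULL)
    if (is.null(mol) || length(mol) == 0L) {
      abort("unparseable SMILES: \"%s\"", s)
    }
    fp <- ChemmineOB::fingerprint_OB(mol, "ECFP4")
    as.numeric(fp)
  })
  native_width <- length(raw[[1L]])
  k <- ceiling(native_width / width)
  folded <- t(vapply(raw, function(bits) {
    bits <- c(bits, numeric(k * width - native_width))
    as.numeric(colSums(matrix(bits, ncol = width, byrow = TRUE)) > 0)
  }, numeric(width)))
  rownames(folded) <- names(smiles) %||% smiles
  folded
}

#' Canonical SMILES via the chemistry toolkit
#'
#' @param smiles character vector of SMILES strings.
#' @return canonical SMILES strings.
#' @export
canonical_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("SMILES canonicalization requires the ChemmineOB package")
  }
  vapply(smiles, function(s) {
    out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))
    strsplit(trimws(out), "[ \t]")[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' |a AND b| / |a OR b|. When both fingerprints are all-zero the
#' similarity is defined as 0 (the conservative "dissimilar" choice).
#'
#' @param a,b binary vectors of equal width.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort("fingerprint widths differ (%d vs %d)", length(a), length(b))
  }
  a <- a > 0
  b <- b > 0
  union <- sum(a | b)
  safe_div(sum(a & b), union)
}

# All-pairs Tanimoto between the rows of binary matrices A (m x w) and
# B (n x w) via popcount algebra; 0/0 pairs map to 0.
tanimoto_matrix <- function(A, B = A) {
  if (ncol(A) != ncol(B)) abort("fingerprint widths differ")
  A <- (A > 0) * 1
  B <- (B > 0) * 1
  inter <- A %*% t(B)
  un <- outer(rowSums(A), rowSums(B), "+") - inter
  sim <- ifelse(un == 0, 0, inter / un)
  rownames(sim) <- rownames(A)
  colnames(sim) <- rownames(B)
  sim
}

#' Random baseline fingerprint
#'
#' i.i.d. Bernoulli bits emulating the sparsity of hashed ECFP4 vectors
#' (about 10% ones in typical bioactivity datasets), used for the
#' random-compound baseline models.
#'
#' @param n number of fingerprints.
#' @param width bits per fingerprint (default 1024).
#' @param p_one probability of a set bit (default 0.1).
#' @param seed integer seed.
#' @return 0/1 matrix `n x width` with rownames `rnd_cmp<k>`.
#' @export
random_fingerprint <- function(n = 1L, width = 1024L, p_one = 0.1, seed = 1L) {
  if (!is_count(n) || !is_count(width)) abort("`n` and `width` must be counts")
  if (!is_prob(p_one)) abort("`p_one` must be in [0, 1]")
  m <- with_seed(seed, matrix(stats::rbinom(n * width, 1L, p_one),
                              nrow = n, ncol = width))
  rownames(m) <- sprintf("rnd_cmp%d", seq_len(n))
  m
}

#' Assemble fingerprints into a compound feature table
#'
#' @param fp 0/1 matrix with compound ids as row names.
#' @return a [feature_table()] of kind `"compound"`.
#' @export
fingerprint_table <- function(fp) {
  if (!all(fp %in% c(0, 1))) abort("fingerprints must be binary")
  feature_table(fp, kind = "compound")
}
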