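## Multiple sequence alignment container and information-theoretic measures.
##
## The symbol set is the 20 standard amino acids expanded with the gap
## character "-" (21st symbol) and one marker "X" collapsing all nonstandard
## residues (22nd symbol).  All entropies and mutual information values are
## in bits (log base 2).

#' Construct an alignment object from character sequences
#'
#' @param seqs character vector of aligned sequences (equal lengths).
#' @param headers optional FASTA headers, kept as metadata.
#' @return Object of class `msa_alignment`: `seqs`, `headers`,
#'   `mat` (S x L integer matrix of symbol codes 1..22), `S`, `L`,
#'   `alphabet`.
#' @export
msa_alignment <- function(seqs, headers = names(seqs)) {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 1L) stop("alignment must contain at least one sequence")
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  if (L == 0L) stop("alignment has zero columns")
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  codes <- match(chars, AA_ALPHABET22)
  n_bad <- sum(is.na(codes))
  if (n_bad > 0L) {
    warning(sprintf("%d character(s) outside the amino-acid alphabet mapped to the nonstandard marker '%s'",
                    n_bad, NONSTD_CHAR))
    codes[is.na(codes)] <- match(NONSTD_CHAR, AA_ALPHABET22)
  }
  mat <- matrix(as.integer(codes), nrow = length(seqs), ncol = L)
  structure(
    list(seqs = apply(matrix(AA_ALPHABET22[mat], nrow = length(seqs)), 1L, paste, collapse = ""),
         headers = if (is.null(headers)) sprintf("seq%d", seq_along(seqs)) else as.character(headers),
         mat = mat, S = length(seqs), L = L, alphabet = AA_ALPHABET22),
    class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns (alphabet of %d symbols)\n",
              x$S, x$L, length(x$alphabet)))
  invisible(x)
}

#' Read a multiple sequence alignment in FASTA format
#'
#' Reads through \pkg{seqinr}; all records must have equal length.
#' Characters outside the 22-symbol alphabet (20 amino acids, gap `-`,
#' nonstandard `X`) are mapped to `X` with a warning.
#'
#' @param source path to a FASTA file, or FASTA text (detected by a leading
#'   `>` or an embedded newline).
#' @return An [msa_alignment()] object.
#' @export
read_alignment <- function(source) {
  if (length(source) == 1L && !grepl("[>\n]", source)) {
    if (!file.exists(source)) stop(sprintf("alignment file not found: %s", source))
    path <- source
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(unlist(strsplit(source, "\n", fixed = TRUE)), path)
  }
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE),
    error = function(e) stop(sprintf("cannot parse FASTA input: %s", conditionMessage(e))))
  if (length(recs) == 0L) stop("empty FASTA input: no records found")
  msa_alignment(unlist(recs, use.names = FALSE), headers = names(recs))
}

#' Marginal and joint column frequencies
#'
#' Relative symbol frequencies for two alignment columns.  The marginals are
#' the row/column sums of the joint table.
#'
#' @param a an [msa_alignment()].
#' @param i,j column indices (1-based).
#' @return list with `p_i`, `p_j` (length-22 named vectors summing to 1) and
#'   `joint` (22 x 22 matrix summing to 1).
#' @export
column_frequencies <- function(a, i, j = i) {
  stopifnot(inherits(a, "msa_alignment"),
            i >= 1L, i <= a$L, j >= 1L, j <= a$L)
  K <- length(a$alphabet)
  xi <- a$mat[, i]
  xj <- a$mat[, j]
  joint <- matrix(tabulate(xi + K * (xj - 1L), K * K) / a$S, K, K,
                  dimnames = list(a$alphabet, a$alphabet))
  list(p_i = rowSums(joint), p_j = colSums(joint), joint = joint)
}

## entropy of a probability vector, in bits; 0 log 0 == 0
#' @noRd
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-column Shannon entropies
#'
#' \eqn{H_i = -\sum_x p_i(x) \log_2 p_i(x)} with the convention
#' \eqn{0 \log 0 = 0}; frequencies are the relative symbol counts within the
#' column.
#'
#' @param a an [msa_alignment()].
#' @return numeric vector of length L, in bits.
#' @export
entropy <- function(a) {
  stopifnot(inherits(a, "msa_alignment"))
  K <- length(a$alphabet)
  apply(a$mat, 2L, function(col) entropy_bits(tabulate(col, K) / a$S))
}

## core MI computation on an integer code matrix; returns list of matrices
#' @noRd
mi_core <- function(mat, K) {
  S <- nrow(mat); L <- ncol(mat)
  H <- apply(mat, 2L, function(col) entropy_bits(tabulate(col, K) / S))
  Hij <- matrix(0, L, L)
  diag(Hij) <- H
  if (L > 1L) {
    for (i in seq_len(L - 1L)) {
      xi <- mat[, i]
      for (j in (i + 1L):L) {
        pj <- tabulate(xi + K * (mat[, j] - 1L), K * K) / S
        Hij[i, j] <- Hij[j, i] <- entropy_bits(pj)
      }
    }
  }
  mi <- outer(H, H, "+") - Hij
  diag(mi) <- H
  ## clamp the tiny negatives that finite-precision subtraction can leave
  mi[mi < 0 & mi > -1e-12] <- 0
  list(entropy = H, joint_entropy = Hij, mi = mi)
}

#' Pairwise mutual information of alignment columns
#'
#' Computes, for every pair of columns (i, j),
#' \deqn{MI_{ij} = \sum_{x,y} p_{ij}(x,y) \log_2
#'       \frac{p_{ij}(x,y)}{p_i(x)\,p_j(y)}}
#' together with the per-column entropies and joint entropies, using the
#' identity \eqn{MI_{ij} = H_i + H_j - H_{ij}} (exact for plug-in
#' frequencies).  The diagonal carries \eqn{MI_{ii} = H_i}.
#'
#' @param a an [msa_alignment()].
#' @param null_shuffles if > 0, also estimate the finite-sample null model by
#'   [mi_null_model()] with this many shuffles.
#' @param seed RNG seed for the null model.
#' @return Object of class `mi_result`: `entropy` (length L, bits),
#'   `joint_entropy` and `mi` (L x L symmetric, bits), and when requested
#'   `null_mean`, `null_sd`.
#' @export
mutual_information <- function(a, null_shuffles = 0L, seed = NULL) {
  stopifnot(inherits(a, "msa_alignment"))
  res <- mi_core(a$mat, length(a$alphabet))
  res$L <- a$L
  res$S <- a$S
  class(res) <- "mi_result"
  if (null_shuffles > 0L) {
    nm <- mi_null_model(a, n_shuffles = null_shuffles, seed = seed)
    res$null_mean <- nm$null_mean
    res$null_sd <- nm$null_sd
  }
  res
}

#' @export
print.mi_result <- function(x, ...) {
  off <- x$mi[upper.tri(x$mi)]
  cat(sprintf("MI result: %d columns, %d sequences; off-diagonal MI in [%.4g, %.4g] bits%s\n",
              x$L, x$S, if (length(off)) min(off) else NA, if (length(off)) max(off) else NA,
              if (!is.null(x$null_mean)) " (null model attached)" else ""))
  invisible(x)
}

#' Finite-sample null model for mutual information
#'
#' Independent within-column permutation: each shuffle permutes the symbols
#' of every column independently, destroying inter-column correlation while
#' preserving the column marginals.  The per-pair mean and standard
#' deviation of MI over shuffles estimate the finite-sample MI bias between
#' independent columns.
#'
#' @param a an [msa_alignment()].
#' @param n_shuffles number of shuffles (default 100).
#' @param seed integer seed for reproducibility.
#' @return list with `null_mean` and `null_sd` (L x L matrices, bits;
#'   `null_sd` is `NA` when `n_shuffles == 1`) and `n_shuffles`.
#' @export
mi_null_model <- function(a, n_shuffles = 100L, seed = NULL) {
  stopifnot(inherits(a, "msa_alignment"), n_shuffles >= 1L)
  K <- length(a$alphabet)
  L <- a$L; S <- a$S
  with_seed(seed, {
    acc <- matrix(0, L, L)
    acc2 <- matrix(0, L, L)
    for (r in seq_len(n_shuffles)) {
      shuf <- apply(a$mat, 2L, function(col) col[sample.int(S)])
      mi <- mi_core(matrix(shuf, nrow = S), K)$mi
      acc <- acc + mi
      acc2 <- acc2 + mi * mi
    }
    m <- acc / n_shuffles
    v <- if (n_shuffles > 1L) (acc2 - n_shuffles * m * m) / (n_shuffles - 1L)
         else matrix(NA_real_, L, L)
    v[v < 0] <- 0  # round-off guard
    list(null_mean = m, null_sd = sqrt(v), n_shuffles = n_shuffles)
  })
}
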