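## Synthetic structures and alignments with known properties, so the whole
## pipeline is testable without any downloads.

#' Specification for a synthetic structure
#'
#' @param topology one of `"chain"` (straight line along x — note this
#'   embedding is mechanically degenerate: all springs are collinear, so it
#'   is meant for format/round-trip work, not for elastic-model tests),
#'   `"helix"` (alpha-helical chain geometry: a generically rigid 3-D
#'   chain), `"ring"` (closed ring with an alternating z pucker so spring
#'   directions span 3-space), `"dimer"` (two parallel helical chains A and
#'   B), `"globule"` (self-avoiding random compact cluster, one chain).
#' @param n_residues bead count (per chain for `"dimer"`).
#' @param spacing consecutive C-alpha distance in Angstrom (default 3.8).
#' @param seed RNG seed (used by `"globule"` and random sequences).
#' @param sequence_model `"fixed"` (repeating 20-letter sequence) or
#'   `"random"` (uniform over the 20 amino acids).
#' @return list of class `toy_spec`.
#' @export
toy_spec <- function(topology = c("chain", "helix", "ring", "dimer", "globule"),
                     n_residues = 10L, spacing = 3.8, seed = 1L,
                     sequence_model = c("fixed", "random")) {
  topology <- match.arg(topology)
  sequence_model <- match.arg(sequence_model)
  stopifnot(n_residues >= 2L, spacing > 0)
  structure(list(topology = topology, n_residues = as.integer(n_residues),
                 spacing = spacing, seed = as.integer(seed),
                 sequence_model = sequence_model),
            class = "toy_spec")
}

## alpha-helix-like backbone: radius 2.3 A, rise 1.5 A, 100 degrees/residue
## gives consecutive C-alpha distances close to `spacing` after rescaling
#' @noRd
helix_coords <- function(n, spacing) {
  theta <- (seq_len(n) - 1L) * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (seq_len(n) - 1L))
  step <- sqrt(sum((xyz[2L, ] - xyz[1L, ])^2))
  xyz * (spacing / step)
}

#' @noRd
globule_coords <- function(n, spacing, min_sep = 3.5) {
  ## self-avoiding chain growth by rejection: each bead at `spacing` from
  ## its predecessor, biased toward the centroid so the cluster stays
  ## compact, re-drawn until it clears `min_sep` from all earlier beads
  xyz <- matrix(0, n, 3L)
  for (i in 2:n) {
    for (try in 1:2000) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u * u))
      toward <- colMeans(xyz[seq_len(i - 1L), , drop = FALSE]) - xyz[i - 1L, ]
      nt <- sqrt(sum(toward * toward))
      if (nt > 1e-9 && stats::runif(1) < 0.5) u <- (u + toward / nt) / sqrt(sum((u + toward / nt)^2))
      cand <- xyz[i - 1L, ] + spacing * u
      d2 <- rowSums((xyz[seq_len(i - 1L), , drop = FALSE] -
                       matrix(cand, i - 1L, 3L, byrow = TRUE))^2)
      d2[i - 1L] <- Inf  # predecessor sits at exactly `spacing`
      if (all(d2 >= min_sep^2)) { xyz[i, ] <- cand; break }
      if (try == 2000) stop("globule placement failed; try another seed")
    }
  }
  xyz
}

#' Generate a synthetic C-alpha structure
#'
#' Deterministic for a given [toy_spec()]; the PDB text round-trips through
#' [read_pdb()] at the 3-decimal coordinate precision of the format.  The
#' random globule is verified connected under the default contact cutoff
#' (every bead reachable through contacts within 13 Angstrom).
#'
#' @param spec a [toy_spec()].
#' @return list with `structure` (a [ca_structure()], coordinates rounded to
#'   3 decimals as in the PDB text) and `pdb_text` (character vector of PDB
#'   lines: fixed wwPDB columns, occupancy 1.00, B-factor 0.00, one TER per
#'   chain).
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_residues
  sp <- spacing <- spec$spacing
  with_seed(spec$seed, {
    if (spec$topology == "chain") {
      coords <- cbind((seq_len(n) - 1L) * sp, 0, 0)
      chains <- rep("A", n)
    } else if (spec$topology == "helix") {
      coords <- helix_coords(n, sp)
      chains <- rep("A", n)
    } else if (spec$topology == "ring") {
      r <- sp / (2 * sin(pi / n))
      th <- 2 * pi * (seq_len(n) - 1L) / n
      pucker <- 0.5 * rep_len(c(-1, 1), n)  # out-of-plane so the ring is 3-D rigid
      coords <- cbind(r * cos(th), r * sin(th), pucker)
      chains <- rep("A", n)
    } else if (spec$topology == "dimer") {
      one <- helix_coords(n, sp)
      coords <- rbind(one, cbind(one[, 1L] + 8, one[, 2L], one[, 3L]))
      chains <- rep(c("A", "B"), each = n)
    } else {  # globule
      repeat {
        coords <- globule_coords(n, sp)
        ## verify connectivity under the default cutoff before accepting
        d2 <- as.matrix(stats::dist(coords))^2
        adj <- d2 <= 169
        reach <- logical(n); reach[1L] <- TRUE
        repeat {
          new <- (adj %*% reach > 0) & !reach
          if (!any(new)) break
          reach <- reach | new
        }
        if (all(reach)) break
      }
      chains <- rep("A", n)
    }
    coords <- round(coords, 3L)
    nres <- nrow(coords)
    seqres <- switch(spec$sequence_model,
      fixed = rep_len(AA20, nres),
      random = sample(AA20, nres, replace = TRUE))
    s <- ca_structure(coords, chains, seqres,
                      residue_numbers = stats::ave(seq_len(nres), chains,
                                                   FUN = seq_along))
    list(structure = s, pdb_text = format_pdb(s))
  })
}

#' Format a C-alpha structure as PDB text
#'
#' Standard fixed columns, occupancy 1.00, B-factor 0.00, one TER record per
#' chain, terminated by END.
#'
#' @param s a [ca_structure()].
#' @param bvalues optional length-N vector written into the B-factor column.
#' @return character vector of PDB lines.
#' @export
format_pdb <- function(s, bvalues = NULL) {
  stopifnot(inherits(s, "ca_structure"))
  b <- if (is.null(bvalues)) rep(0, s$n) else as.numeric(bvalues)
  stopifnot(length(b) == s$n)
  lines <- character(0)
  serial <- 0L
  for (ch in rle(s$chain_ids)$values) {
    idx <- which(s$chain_ids == ch)
    for (i in idx) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, aa1to3(s$residue_names[i]), ch, s$residue_numbers[i],
        s$coords[i, 1L], s$coords[i, 2L], s$coords[i, 3L], 1, b[i]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial, aa1to3(s$residue_names[idx[length(idx)]]),
                              ch, s$residue_numbers[idx[length(idx)]]))
  }
  c(lines, "END")
}

#' Generate a synthetic alignment with planted covariation
#'
#' Columns are independent uniform draws over the 20 amino acids, except the
#' listed column pairs: with probability `coupling` the second column's
#' symbol is a fixed permutation image of the first column's symbol (perfect
#' covariation), otherwise it is drawn independently.  At `coupling = 1` the
#' population MI of a planted pair equals the first column's entropy; at
#' `coupling = 0` the pair is independent.
#'
#' @param L alignment length (columns).
#' @param S number of sequences.
#' @param covarying 2-column matrix (or list of length-2 vectors) of column
#'   pairs to couple; columns may appear in at most one pair.
#' @param coupling coupling strength in [0, 1].
#' @param seed RNG seed; same seed, same alignment.
#' @return an [msa_alignment()].
#' @export
make_alignment <- function(L, S, covarying = NULL, coupling = 1,
                           seed = 1L) {
  stopifnot(L >= 1L, S >= 1L, coupling >= 0, coupling <= 1)
  if (is.list(covarying)) covarying <- do.call(rbind, covarying)
  if (!is.null(covarying)) {
    covarying <- matrix(as.integer(covarying), ncol = 2L)
    stopifnot(all(covarying >= 1L), all(covarying <= L))
    if (anyDuplicated(as.vector(covarying)))
      stop("each column may appear in at most one covarying pair")
  }
  with_seed(seed, {
    mat <- matrix(sample(AA20, S * L, replace = TRUE), nrow = S, ncol = L)
    if (!is.null(covarying)) {
      perm <- c(AA20[-1L], AA20[1L])  # fixed bijection on the alphabet
      names(perm) <- AA20
      for (p in seq_len(nrow(covarying))) {
        i <- covarying[p, 1L]; j <- covarying[p, 2L]
        linked <- stats::runif(S) < coupling
        mat[linked, j] <- perm[mat[linked, i]]
      }
    }
    msa_alignment(apply(mat, 1L, paste, collapse = ""))
  })
}

#' Write an alignment to FASTA
#'
#' @param a an [msa_alignment()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(a, file) {
  stopifnot(inherits(a, "msa_alignment"))
  out <- character(2L * a$S)
  out[c(TRUE, FALSE)] <- paste0(">", a$headers)
  out[c(FALSE, TRUE)] <- a$seqs
  writeLines(out, file)
  invisible(file)
}
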