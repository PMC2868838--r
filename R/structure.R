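## Cα-level structure model and contact construction.

#' Construct a C-alpha structure object
#'
#' Low-level constructor used by [read_pdb()] and the fixture generator.
#' Each residue is one bead at its C-alpha position.
#'
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param chain_ids character vector of per-residue chain labels; residues of
#'   one chain must form a contiguous run.
#' @param residue_names per-residue one-letter amino-acid codes (20 standard
#'   letters or `"X"` for nonstandard residues).
#' @param residue_numbers integer residue numbers from the source file
#'   (author numbering); defaults to 1..N.
#' @param insert per-residue insertion codes (`""` when absent).
#' @return An object of class `ca_structure` with fields `coords`,
#'   `chain_ids`, `residue_names`, `residue_numbers`, `insert`, `n`.
#' @export
ca_structure <- function(coords, chain_ids, residue_names,
                         residue_numbers = seq_len(nrow(coords)),
                         insert = rep("", nrow(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 2L) stop("a C-alpha structure needs at least two residues")
  if (ncol(coords) != 3L) stop("'coords' must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  chain_ids <- as.character(chain_ids)
  residue_names <- toupper(as.character(residue_names))
  stopifnot(length(chain_ids) == n, length(residue_names) == n,
            length(residue_numbers) == n, length(insert) == n)
  bad <- !(residue_names %in% c(AA20, NONSTD_CHAR))
  if (any(bad)) {
    residue_names[bad] <- NONSTD_CHAR
  }
  ## chains must be contiguous runs
  runs <- rle(chain_ids)$values
  if (anyDuplicated(runs)) {
    stop("chain identifiers must group residues into contiguous runs")
  }
  structure(
    list(coords = unname(coords),
         chain_ids = chain_ids,
         residue_names = residue_names,
         residue_numbers = as.integer(residue_numbers),
         insert = as.character(insert),
         n = n),
    class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  ch <- rle(x$chain_ids)
  cat(sprintf("C-alpha structure: %d residues, %d chain(s) [%s]\n",
              x$n, length(ch$values),
              paste(sprintf("%s:%d", ch$values, ch$lengths), collapse = ", ")))
  invisible(x)
}

#' Read a PDB file into a C-alpha bead model
#'
#' Parses ATOM/HETATM records (wwPDB v3.3 fixed columns, through
#' \pkg{bio3d}) and keeps one bead per residue at its C-alpha atom, in file
#' order.  Three-letter residue names are mapped to one-letter codes; any
#' residue outside the 20 standard amino acids (e.g. MSE) is kept and mapped
#' to the nonstandard marker `"X"`.  For altLoc duplicates the first
#' occurrence per residue is kept; insertion codes are honored as distinct
#' residues in file order.
#'
#' @param source path to a PDB file, or a character vector of PDB lines
#'   (anything containing a newline, or of length > 1, is treated as text).
#' @return A [ca_structure()] object.
#' @seealso [select_chains()], [build_contacts()]
#' @examples
#' pdb <- make_structure(toy_spec("helix", 5))$pdb_text
#' read_pdb(pdb)
#' @export
read_pdb <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records found in PDB input")
  ## validate coordinate fields before handing over to the parser
  for (k in which(is_atom)) {
    ln <- lines[k]
    if (nchar(ln) < 54) stop(sprintf("malformed ATOM record (short line) at line %d", k))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("malformed coordinate fields at line %d: %s", k, ln))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha ATOM records found in PDB input")
  ca$chain[is.na(ca$chain)] <- " "
  ca$insert[is.na(ca$insert)] <- ""
  ## first altLoc/duplicate C-alpha per (chain, resno, insert) wins
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  ca <- ca[!duplicated(key), , drop = FALSE]
  if (nrow(ca) < 2L) stop("fewer than two C-alpha records in PDB input")
  ca_structure(coords = cbind(ca$x, ca$y, ca$z),
               chain_ids = ca$chain,
               residue_names = aa3to1(ca$resid),
               residue_numbers = ca$resno,
               insert = ca$insert)
}

#' Select chains from a structure
#'
#' Subsets the beads of the requested chains in their original file order and
#' re-bases the internal indices to 1..N'.
#'
#' @param s a [ca_structure()].
#' @param chains character vector of chain labels; each must occur in `s`.
#' @return A [ca_structure()] restricted to the requested chains.
#' @export
select_chains <- function(s, chains) {
  stopifnot(inherits(s, "ca_structure"))
  chains <- as.character(chains)
  missing <- setdiff(chains, unique(s$chain_ids))
  if (length(missing) > 0L)
    stop(sprintf("chain label(s) not present in structure: %s",
                 paste(missing, collapse = ", ")))
  keep <- s$chain_ids %in% chains
  ca_structure(coords = s$coords[keep, , drop = FALSE],
               chain_ids = s$chain_ids[keep],
               residue_names = s$residue_names[keep],
               residue_numbers = s$residue_numbers[keep],
               insert = s$insert[keep])
}

#' Build the covalent/non-covalent contact model
#'
#' Covalent pairs are all sequence-adjacent beads (i, i+1) within one chain
#' (chain breaks in the author numbering still yield a covalent pair: the
#' bead-chain abstraction defines covalency by adjacency).  Non-covalent
#' contacts are all remaining pairs whose squared native distance is
#' `<= cutoff_sq`; the comparison is on squared distance, so the default
#' `cutoff_sq = 169` corresponds to a 13 Angstrom cutoff.
#'
#' @param s a [ca_structure()].
#' @param cutoff_sq squared distance cutoff in Angstrom^2 (default 169).
#' @return An object of class `contact_model` with fields
#'   `covalent` (m x 2 index matrix, i < j), `noncovalent` (k x 2 matrix),
#'   `covalent_dist`, `noncovalent_dist` (native distances in Angstrom),
#'   `cutoff_sq`, and `n`.  All indices are 1-based bead indices of `s`.
#' @export
build_contacts <- function(s, cutoff_sq = 169) {
  stopifnot(inherits(s, "ca_structure"), cutoff_sq > 0)
  n <- s$n
  d2 <- as.matrix(stats::dist(s$coords))^2
  cov_i <- which(s$chain_ids[-n] == s$chain_ids[-1L])
  covalent <- cbind(i = cov_i, j = cov_i + 1L)
  in_cut <- which(upper.tri(d2) & d2 <= cutoff_sq, arr.ind = TRUE)
  ## drop the covalent pairs from the cutoff set
  if (nrow(covalent) > 0L) {
    cov_key <- covalent[, 1L] + n * covalent[, 2L]
    keep <- !((in_cut[, 1L] + n * in_cut[, 2L]) %in% cov_key)
    in_cut <- in_cut[keep, , drop = FALSE]
  }
  noncovalent <- cbind(i = as.integer(in_cut[, 1L]), j = as.integer(in_cut[, 2L]))
  o <- order(noncovalent[, 1L], noncovalent[, 2L])
  noncovalent <- noncovalent[o, , drop = FALSE]
  structure(
    list(covalent = covalent,
         noncovalent = noncovalent,
         covalent_dist = sqrt(d2[covalent]),
         noncovalent_dist = sqrt(d2[noncovalent]),
         cutoff_sq = cutoff_sq,
         n = n),
    class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf(paste0("Contact model: %d residues, %d covalent pairs, ",
                     "%d non-covalent contacts (cutoff^2 = %g A^2)\n"),
              x$n, nrow(x$covalent), nrow(x$noncovalent), x$cutoff_sq))
  invisible(x)
}

#' Export a contact model as a data frame
#'
#' @param x a `contact_model`.
#' @param ... unused.
#' @return data frame with columns `i`, `j`, `kind` (`"covalent"` or
#'   `"contact"`), `distance`.
#' @export
as.data.frame.contact_model <- function(x, ...) {
  data.frame(
    i = c(x$covalent[, 1L], x$noncovalent[, 1L]),
    j = c(x$covalent[, 2L], x$noncovalent[, 2L]),
    kind = rep(c("covalent", "contact"),
               c(nrow(x$covalent), nrow(x$noncovalent))),
    distance = c(x$covalent_dist, x$noncovalent_dist))
}
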