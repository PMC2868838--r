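## In-silico perturbations: contact breaking, point mutation, Frobenius-norm
## scoring, the MI-ranked batch protocol, and the four-quadrant MI/FN
## classification.

#' Break a single non-covalent contact
#'
#' Returns a copy of the contact model with one non-covalent pair removed;
#' the input is not modified.  Covalent pairs cannot be broken.
#'
#' @param contacts a [build_contacts()] model.
#' @param pair length-2 index vector (i, j); order-insensitive.
#' @return a `contact_model` with `nrow(noncovalent)` reduced by one.
#' @export
break_contact <- function(contacts, pair) {
  stopifnot(inherits(contacts, "contact_model"), length(pair) == 2L)
  i <- min(pair); j <- max(pair)
  if (nrow(contacts$covalent) > 0L &&
      any(contacts$covalent[, 1L] == i & contacts$covalent[, 2L] == j))
    stop(sprintf("pair (%d, %d) is covalent and cannot be broken", i, j))
  hit <- which(contacts$noncovalent[, 1L] == i & contacts$noncovalent[, 2L] == j)
  if (length(hit) != 1L)
    stop(sprintf("pair (%d, %d) is not a non-covalent contact of the model", i, j))
  contacts$noncovalent <- contacts$noncovalent[-hit, , drop = FALSE]
  contacts$noncovalent_dist <- contacts$noncovalent_dist[-hit]
  contacts
}

#' Mutate one position of the sequence
#'
#' Coordinates and contacts are untouched; only the residue identity (and
#' hence the spring constants involving that site) changes downstream.
#'
#' @param s a [ca_structure()].
#' @param position bead index (1-based).
#' @param new_residue one-letter amino-acid code (or `"X"`).
#' @return a modified `ca_structure`.
#' @export
mutate_sequence <- function(s, position, new_residue) {
  stopifnot(inherits(s, "ca_structure"),
            position >= 1L, position <= s$n)
  new_residue <- toupper(new_residue)
  if (!(new_residue %in% c(AA20, NONSTD_CHAR)))
    stop(sprintf("invalid residue code '%s'", new_residue))
  s$residue_names[position] <- new_residue
  s
}

#' Frobenius norm of a covariance difference
#'
#' \eqn{f = \sqrt{\sum_{kl} (m_1 - m_2)^2_{kl}}}, optionally restricted to
#' the 3x3 blocks whose row and column residues both belong to `subset`
#' (per-subset mechanical scoring).
#'
#' @param m1,m2 equal-shape matrices (typically 3N x 3N covariances).
#' @param subset optional residue-index vector; `NULL` means all residues.
#' @return non-negative scalar.
#' @export
frobenius_norm <- function(m1, m2, subset = NULL) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!identical(dim(m1), dim(m2))) stop("matrix shapes differ")
  d <- m1 - m2
  if (!is.null(subset)) {
    n <- nrow(m1) / 3L
    subset <- as.integer(subset)
    if (any(subset < 1L | subset > n)) stop("subset indices out of range")
    idx <- as.vector(outer(1:3, 3L * (subset - 1L), "+"))
    d <- d[idx, idx, drop = FALSE]
  }
  sqrt(sum(d * d))
}

#' Batch contact-breaking protocol
#'
#' Computes the wild-type covariance once, then for each listed non-covalent
#' pair removes that single contact, rebuilds and re-solves the network, and
#' records the Frobenius norm of the covariance change (and optionally the
#' perturbed B-factors).  All pairs are validated before any computation
#' starts.  Results are a pure function of (structure, spec, pair list):
#' record order follows the pair list and is identical for any worker count.
#'
#' @param s a [ca_structure()].
#' @param spec an [interaction_spec()].
#' @param pairs 2-column index matrix (or list of length-2 vectors) of
#'   non-covalent contacts to break.
#' @param contacts optional precomputed wild-type [build_contacts()] model.
#' @param write_bfactors record perturbed B-factors in each result?
#' @param compute_fnorm record Frobenius norms? (default `TRUE`)
#' @param workers parallel workers (forked via \pkg{parallel}; 1 = serial).
#' @param subset optional residue subset for the Frobenius norm.
#' @return list of `perturbation_record` objects (fields `kind`, `target`,
#'   `fnorm`, `bfactors`); see [as.data.frame.perturbation_batch()].
#' @export
run_break_protocol <- function(s, spec, pairs, contacts = NULL,
                               write_bfactors = FALSE, compute_fnorm = TRUE,
                               workers = 1L, subset = NULL) {
  stopifnot(inherits(s, "ca_structure"), inherits(spec, "interaction_spec"))
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("'pairs' must have two columns (i, j)")
  storage.mode(pairs) <- "integer"
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  if (is.null(contacts)) contacts <- build_contacts(s, spec$cutoff_sq)
  ## fail fast: every pair must be a wild-type non-covalent contact
  key <- contacts$noncovalent[, 1L] + contacts$n * contacts$noncovalent[, 2L]
  bad <- which(!((pairs[, 1L] + contacts$n * pairs[, 2L]) %in% key))
  if (length(bad) > 0L)
    stop(sprintf("pair(s) not in the non-covalent contact set: %s",
                 paste(sprintf("(%d,%d)", pairs[bad, 1L], pairs[bad, 2L]),
                       collapse = " ")))
  wt <- solve_enm(s, contacts, spec)
  one <- function(r) {
    mut <- solve_enm(s, break_contact(contacts, pairs[r, ]), spec)
    structure(
      list(kind = "break",
           target = pairs[r, ],
           fnorm = if (compute_fnorm)
             frobenius_norm(wt$covariance, mut$covariance, subset = subset)
           else NA_real_,
           bfactors = if (write_bfactors) mut$bfactors else NULL),
      class = "perturbation_record")
  }
  idx <- seq_len(nrow(pairs))
  records <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, one, mc.cores = workers)
  } else {
    lapply(idx, one)
  }
  structure(records, class = "perturbation_batch")
}

#' @export
print.perturbation_record <- function(x, ...) {
  cat(sprintf("Perturbation [%s] target (%s): fnorm = %s\n",
              x$kind, paste(x$target, collapse = ", "),
              format(x$fnorm)))
  invisible(x)
}

#' Tabulate a perturbation batch
#'
#' @param x a `perturbation_batch` from [run_break_protocol()].
#' @param ... unused.
#' @return data frame with columns `i`, `j`, `fnorm`.
#' @export
as.data.frame.perturbation_batch <- function(x, ...) {
  data.frame(i = vapply(x, function(r) r$target[1L], integer(1)),
             j = vapply(x, function(r) r$target[2L], integer(1)),
             fnorm = vapply(x, function(r) r$fnorm, numeric(1)))
}

#' Select the contacts with the highest mutual information
#'
#' Ranks the non-covalent contacts of `contacts` by the MI of the
#' corresponding alignment-column pair and returns the top `n`, descending;
#' ties are broken by (i, j) lexicographic order for determinism.
#'
#' Alignment columns map to residues by chain-local position: residue k of
#' each chain reads column k (so for a homo-dimer both chains read the same
#' columns).  Supply `position_map` (alignment column per bead) to override.
#'
#' @param mi an `mi_result` from [mutual_information()].
#' @param contacts a [build_contacts()] model.
#' @param n number of contacts to return; if it exceeds the contact count,
#'   all contacts are returned with a warning.
#' @param position_map optional integer vector, length `contacts$n`.
#' @param chain_ids chain labels used for the default chain-local map; taken
#'   from the structure the contacts were built on.
#' @return matrix with columns `i`, `j`, `mi`, ordered by decreasing MI.
#' @export
select_top_mi_contacts <- function(mi, contacts, n, position_map = NULL,
                                   chain_ids = NULL) {
  stopifnot(inherits(mi, "mi_result"), inherits(contacts, "contact_model"))
  nres <- contacts$n
  if (is.null(position_map)) {
    position_map <- if (is.null(chain_ids)) seq_len(nres)
                    else stats::ave(seq_len(nres), chain_ids,
                                    FUN = seq_along)
  }
  position_map <- as.integer(position_map)
  stopifnot(length(position_map) == nres)
  if (any(position_map < 1L | position_map > mi$L))
    stop("position map exceeds the alignment length")
  nc <- contacts$noncovalent
  if (n > nrow(nc)) {
    warning(sprintf("requested %d contacts but only %d exist; returning all",
                    n, nrow(nc)))
    n <- nrow(nc)
  }
  vals <- mi$mi[cbind(position_map[nc[, 1L]], position_map[nc[, 2L]])]
  o <- order(-vals, nc[, 1L], nc[, 2L])[seq_len(n)]
  cbind(i = nc[o, 1L], j = nc[o, 2L], mi = vals[o])
}

#' Four-quadrant MI/FN classification
#'
#' Min-max normalizes the batch's MI and Frobenius-norm values to [0, 1] and
#' assigns each pair to the nearest of the four corner points (1,1) = 45
#' degrees (high MI, high FN: coevolving and mechanically important),
#' (0,1) = 135 (mechanically important without coevolution), (0,0) = 225
#' (neither), (1,0) = 315 (coevolving, mechanically silent).  Euclidean
#' distance; exact ties go to the higher-MI corner, then the higher-FN
#' corner.  A degenerate batch axis (zero range) normalizes to 0.5.
#'
#' @param records a `perturbation_batch` from [run_break_protocol()].
#' @param mi an `mi_result`.
#' @param position_map,chain_ids as in [select_top_mi_contacts()].
#' @return data frame with columns `i`, `j`, `mi`, `fnorm`, `quadrant`
#'   (factor with levels `"45"`, `"135"`, `"225"`, `"315"`).
#' @export
annotate_quadrants <- function(records, mi, position_map = NULL,
                               chain_ids = NULL) {
  df <- as.data.frame(records)
  if (nrow(df) < 2L)
    stop("quadrant normalization needs at least two records")
  if (any(is.na(df$fnorm)))
    stop("records carry no Frobenius norms (rerun with compute_fnorm = TRUE)")
  nres <- max(df$j)
  if (is.null(position_map)) {
    position_map <- if (is.null(chain_ids)) seq_len(max(df$i, df$j))
                    else stats::ave(seq_along(chain_ids), chain_ids,
                                    FUN = seq_along)
  }
  df$mi <- mi$mi[cbind(position_map[df$i], position_map[df$j])]
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1L]) / diff(r)
  }
  x <- norm01(df$mi)      # MI axis
  y <- norm01(df$fnorm)   # FN axis
  ## corners in tie-preference order: higher-MI first, then higher-FN
  corners <- rbind("45" = c(1, 1), "315" = c(1, 0),
                   "135" = c(0, 1), "225" = c(0, 0))
  df$quadrant <- factor(vapply(seq_along(x), function(k) {
    d2 <- (x[k] - corners[, 1L])^2 + (y[k] - corners[, 2L])^2
    rownames(corners)[which(d2 <= min(d2) + 1e-12)[1L]]
  }, character(1)), levels = c("45", "135", "225", "315"))
  df
}

#' MI-ranked contact-breaking protocol (one call)
#'
#' The full workflow: read/accept an alignment and a structure, compute MI,
#' select the chains of interest, build contacts, pick the `top` contacts
#' with the highest MI, break them one at a time, score each by the
#' Frobenius norm of the covariance change, and classify the (MI, FN) pairs
#' into the four quadrants.
#'
#' @param structure a [ca_structure()] or a PDB path/text.
#' @param alignment an [msa_alignment()] or a FASTA path/text.
#' @param chains optional chain labels to select from the structure.
#' @param top number of top-MI contacts to break (default 400, capped at the
#'   contact count).
#' @param spec an [interaction_spec()]; default parameters `alpha = 82`,
#'   `cutoff_sq = 169`, MJ intra / KE inter, no averaging.
#' @param write_bfactors,workers passed to [run_break_protocol()].
#' @param position_map optional bead-to-column map (default: chain-local
#'   position).
#' @return list with `records` (the batch), `table` (data frame `i`, `j`,
#'   `mi`, `fnorm`, `quadrant`), `mi`, `contacts`, `structure`.
#' @export
simc <- function(structure, alignment, chains = NULL, top = 400L,
                 spec = interaction_spec(), write_bfactors = FALSE,
                 workers = 1L, position_map = NULL) {
  s <- if (inherits(structure, "ca_structure")) structure else read_pdb(structure)
  if (!is.null(chains)) s <- select_chains(s, chains)
  a <- if (inherits(alignment, "msa_alignment")) alignment else read_alignment(alignment)
  mi <- mutual_information(a)
  contacts <- build_contacts(s, spec$cutoff_sq)
  sel <- suppressWarnings(
    select_top_mi_contacts(mi, contacts, top, position_map = position_map,
                           chain_ids = s$chain_ids))
  records <- run_break_protocol(s, spec, sel[, c("i", "j"), drop = FALSE],
                                contacts = contacts,
                                write_bfactors = write_bfactors,
                                workers = workers)
  pm <- position_map
  if (is.null(pm)) pm <- stats::ave(seq_len(s$n), s$chain_ids, FUN = seq_along)
  tab <- annotate_quadrants(records, mi, position_map = pm)
  list(records = records, table = tab, mi = mi, contacts = contacts,
       structure = s)
}
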