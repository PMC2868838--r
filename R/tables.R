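## Amino-acid interaction-strength tables and the elastic model parameter set.

#' Load a 20x20 amino-acid interaction-strength table
#'
#' Returns a symmetric 20x20 matrix of positive pair weights keyed by
#' one-letter amino-acid codes, used as sequence-specific spring constants
#' for non-covalent contacts.
#'
#' Shipped tables:
#' \describe{
#'   \item{`"MJ"`}{magnitudes of the Miyazawa-Jernigan (1996) residue-residue
#'     contact energies (RT units); the default intra-chain weights.}
#'   \item{`"KE"`}{the default inter-chain weights.  The file shipped here is
#'     a \emph{synthetic stand-in} (the MJ magnitudes scaled by 0.9), not the
#'     published Keskin et al. values; it preserves the MJ rank ordering while
#'     mimicking weaker inter-chain contacts.  Supply the published table via
#'     `source` for production inter-chain work.}
#' }
#'
#' @param name `"MJ"`, `"KE"`, or `"custom"` (then `source` is required).
#' @param source for `"custom"`: a path to a whitespace/tab-delimited labeled
#'   20x20 matrix (one-letter row/column labels, `#` comments allowed), or a
#'   labeled numeric matrix.
#' @return 20x20 symmetric numeric matrix with one-letter dimnames, all
#'   entries > 0.
#' @export
load_interaction_tables <- function(name = c("MJ", "KE", "custom"),
                                    source = NULL) {
  name <- match.arg(name)
  if (name %in% c("MJ", "KE")) {
    file <- system.file("extdata",
                        if (name == "MJ") "mj_contact_energies.txt"
                        else "ke_synthetic_contact_energies.txt",
                        package = "coevomech", mustWork = TRUE)
    tab <- utils::read.table(file, header = TRUE, row.names = 1L,
                             comment.char = "#", check.names = FALSE)
    tab <- as.matrix(tab)
  } else {
    if (is.null(source)) stop("a custom table requires 'source'")
    tab <- if (is.matrix(source)) source else {
      as.matrix(utils::read.table(source, header = TRUE, row.names = 1L,
                                  comment.char = "#", check.names = FALSE))
    }
  }
  storage.mode(tab) <- "double"
  if (!identical(dim(tab), c(20L, 20L)))
    stop("interaction table must be 20x20")
  if (is.null(rownames(tab)) || is.null(colnames(tab)) ||
      !setequal(rownames(tab), AA20) || !setequal(colnames(tab), AA20))
    stop("interaction table must be labeled with the 20 one-letter amino-acid codes")
  tab <- tab[AA20, AA20]
  if (!isSymmetric(unname(tab), tol = 1e-10))
    stop("interaction table must be symmetric")
  if (any(!is.finite(tab)) || any(tab <= 0))
    stop("interaction table entries must be positive finite weights (store energy magnitudes)")
  tab
}

## extend a 20x20 table with the nonstandard marker: its row/column is the
## column mean of the table (keeps the Hessian defined for e.g. MSE beads)
#' @noRd
extend_table_nonstd <- function(tab) {
  ext <- matrix(0, 21, 21,
                dimnames = list(c(AA20, NONSTD_CHAR), c(AA20, NONSTD_CHAR)))
  ext[AA20, AA20] <- tab
  cm <- colMeans(tab)
  ext[NONSTD_CHAR, AA20] <- cm
  ext[AA20, NONSTD_CHAR] <- cm
  ext[NONSTD_CHAR, NONSTD_CHAR] <- mean(tab)
  ext
}

#' Elastic-model interaction specification
#'
#' Bundles the parameters of the sequence-specific anisotropic network model:
#' the covalent (peptide-bond) spring strength `alpha`, the squared contact
#' cutoff, and the intra-/inter-chain amino-acid weight tables.
#'
#' @param alpha covalent spring constant (default 82).
#' @param cutoff_sq squared contact cutoff in Angstrom^2 (default 169, i.e.
#'   13 Angstrom).
#' @param intra_table,inter_table table name (`"MJ"`/`"KE"`) or a 20x20
#'   labeled matrix as accepted by [load_interaction_tables()]; defaults MJ
#'   for intra-chain and KE for inter-chain contacts.
#' @param average_tables if `TRUE`, both tables are replaced by their
#'   elementwise mean (the `mj.avg` option).
#' @return Object of class `interaction_spec` with fields `alpha`,
#'   `cutoff_sq`, `intra_table`, `inter_table` (21x21, extended with the
#'   nonstandard marker), `average_tables`.
#' @export
interaction_spec <- function(alpha = 82, cutoff_sq = 169,
                             intra_table = "MJ", inter_table = "KE",
                             average_tables = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(cutoff_sq), length(cutoff_sq) == 1L, cutoff_sq > 0)
  resolve <- function(x) {
    if (is.character(x) && length(x) == 1L && x %in% c("MJ", "KE"))
      load_interaction_tables(x)
    else load_interaction_tables("custom", source = x)
  }
  intra <- resolve(intra_table)
  inter <- resolve(inter_table)
  if (isTRUE(average_tables)) {
    avg <- (intra + inter) / 2
    intra <- inter <- avg
  }
  structure(
    list(alpha = alpha, cutoff_sq = cutoff_sq,
         intra_table = extend_table_nonstd(intra),
         inter_table = extend_table_nonstd(inter),
         average_tables = isTRUE(average_tables)),
    class = "interaction_spec")
}

#' @export
print.interaction_spec <- function(x, ...) {
  cat(sprintf("Interaction spec: alpha = %g, cutoff^2 = %g A^2, averaging %s\n",
              x$alpha, x$cutoff_sq, if (x$average_tables) "on" else "off"))
  invisible(x)
}

#' Spring constant for a residue pair
#'
#' Covalent pairs get the backbone strength `alpha`; other pairs get the
#' intra- or inter-chain table entry for the unordered residue pair.
#' Nonstandard residues (`"X"`) use the table's column means.
#'
#' @param spec an [interaction_spec()].
#' @param res_i,res_j one-letter residue codes.
#' @param same_chain logical: are the residues on the same chain?
#' @param covalent logical: sequence-adjacent (peptide-bonded) pair?
#' @return positive numeric weight.
#' @export
spring_constant <- function(spec, res_i, res_j, same_chain = TRUE,
                            covalent = FALSE) {
  stopifnot(inherits(spec, "interaction_spec"))
  if (covalent) return(spec$alpha)
  tab <- if (same_chain) spec$intra_table else spec$inter_table
  ri <- toupper(res_i); rj <- toupper(res_j)
  ri[!(ri %in% rownames(tab))] <- NONSTD_CHAR
  rj[!(rj %in% rownames(tab))] <- NONSTD_CHAR
  tab[cbind(ri, rj)]
}
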