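## Sequence-specific anisotropic network model: Hessian, eigenmodes,
## pseudo-inverse covariance, isotropic B-factors.
##
## The harmonic potential is
##   V = sum_covalent alpha/2 (s - s0)^2 + sum_C kappa_ij/2 (s - s0)^2
## with s0 the native C-alpha distance.  The Hessian at the native state has
## off-diagonal 3x3 blocks -(k/s0^2) d d^T = -k u u^T (u the native unit
## separation vector) and diagonal blocks that cancel the row sums, so rigid
## translations/rotations cost nothing.

## isotropic B-factor prefactor 8*pi^2/3 (kept in one place; relative
## profiles do not depend on it)
BFAC_PREFACTOR <- 8 * pi^2 / 3

## per-pair spring constants for a contact model, in the order
## (covalent pairs, non-covalent pairs)
#' @noRd
pair_constants <- function(s, contacts, spec) {
  nc <- contacts$noncovalent
  same <- s$chain_ids[nc[, 1L]] == s$chain_ids[nc[, 2L]]
  k_nc <- numeric(nrow(nc))
  if (nrow(nc) > 0L) {
    k_nc[same] <- spring_constant(spec, s$residue_names[nc[same, 1L]],
                                  s$residue_names[nc[same, 2L]],
                                  same_chain = TRUE)
    k_nc[!same] <- spring_constant(spec, s$residue_names[nc[!same, 1L]],
                                   s$residue_names[nc[!same, 2L]],
                                   same_chain = FALSE)
  }
  list(covalent = rep(spec$alpha, nrow(contacts$covalent)),
       noncovalent = k_nc)
}

## assemble the 3N x 3N Hessian from explicit pair lists and constants
#' @noRd
hessian_from_pairs <- function(coords, pairs, k) {
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    d <- coords[i, ] - coords[j, ]
    s2 <- sum(d * d)
    if (s2 <= 0)
      stop(sprintf("coincident beads %d and %d: zero native distance", i, j))
    blk <- (k[p] / s2) * tcrossprod(d)
    bi <- (3L * (i - 1L) + 1L):(3L * i)
    bj <- (3L * (j - 1L) + 1L):(3L * j)
    H[bi, bj] <- H[bi, bj] - blk
    H[bj, bi] <- H[bj, bi] - blk
    H[bi, bi] <- H[bi, bi] + blk
    H[bj, bj] <- H[bj, bj] + blk
  }
  H
}

#' Build the ANM Hessian
#'
#' Assembles the 3N x 3N Hessian of the harmonic network: covalent
#' (sequence-adjacent) pairs with spring constant `alpha`, non-covalent
#' contacts with the sequence-specific table weights of `spec`.
#'
#' @param s a [ca_structure()].
#' @param contacts a [build_contacts()] model derived from `s`.
#' @param spec an [interaction_spec()].
#' @return symmetric positive-semidefinite 3N x 3N matrix.
#' @export
build_hessian <- function(s, contacts, spec) {
  stopifnot(inherits(s, "ca_structure"), inherits(contacts, "contact_model"),
            inherits(spec, "interaction_spec"), contacts$n == s$n)
  k <- pair_constants(s, contacts, spec)
  hessian_from_pairs(s$coords,
                     rbind(contacts$covalent, contacts$noncovalent),
                     c(k$covalent, k$noncovalent))
}

#' Eigendecomposition of a symmetric Hessian
#'
#' For the symmetric positive-semidefinite Hessian the singular value
#' decomposition and the eigendecomposition coincide; `eigen()` on the
#' symmetric matrix is used.  Eigenvalues are returned ascending with
#' orthonormal eigenvectors in matching column order.
#'
#' @param h symmetric matrix.
#' @param tol symmetry tolerance relative to the largest entry.
#' @return list with `values` (ascending) and `vectors`.
#' @export
decompose <- function(h, tol = 1e-8) {
  h <- as.matrix(h)
  scale <- max(abs(h), 1)
  if (max(abs(h - t(h))) > tol * scale)
    stop("matrix is not symmetric within tolerance")
  e <- eigen((h + t(h)) / 2, symmetric = TRUE)
  idx <- rev(seq_along(e$values))
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}

#' Covariance matrix from eigenmodes (Moore-Penrose pseudo-inverse)
#'
#' \deqn{M = \sum_{k > n_{skip}} \lambda_k^{-1} v_k v_k^T}
#' over the ascending eigenvalues, skipping the `n_skip` smallest modes.
#' For a connected structure these are the six vanishing rigid-body modes
#' (three translations, three rotations), so `M` is the Moore-Penrose
#' pseudo-inverse of the Hessian.  A skipped mode with a non-negligible
#' eigenvalue (relative to the largest) triggers a warning: the model is
#' disconnected or pre-stressed.
#'
#' @param sol list with `values` (ascending) and `vectors`, as returned by
#'   [decompose()].
#' @param n_skip number of low modes to drop (default 6).
#' @param zero_tol relative threshold used for the sanity warning.
#' @return 3N x 3N symmetric covariance matrix.
#' @export
covariance_from_modes <- function(sol, n_skip = 6L, zero_tol = 1e-8) {
  vals <- sol$values
  if (length(vals) <= n_skip)
    stop(sprintf("need more than %d modes, got %d", n_skip, length(vals)))
  if (is.unsorted(vals, strictly = FALSE))
    stop("eigenvalues must be ascending")
  lam_max <- vals[length(vals)]
  if (n_skip > 0L && vals[n_skip] > zero_tol * lam_max)
    warning(sprintf(paste0("skipped mode %d has eigenvalue %.3g ",
                           "(> %.0e x lambda_max): disconnected or pre-stressed model"),
                    n_skip, vals[n_skip], zero_tol))
  keep <- (n_skip + 1L):length(vals)
  V <- sol$vectors[, keep, drop = FALSE]
  M <- V %*% (t(V) / vals[keep])
  (M + t(M)) / 2
}

#' Isotropic B-factors from a covariance matrix
#'
#' \eqn{B_i = (8\pi^2/3)\,(M^{ii}_{xx} + M^{ii}_{yy} + M^{ii}_{zz})}: the
#' trace of residue i's diagonal 3x3 block, scaled by the conventional
#' isotropic prefactor.
#'
#' @param m 3N x 3N covariance matrix.
#' @return numeric vector of length N.
#' @export
bfactors <- function(m) {
  d <- diag(as.matrix(m))
  if (length(d) %% 3L != 0L) stop("covariance matrix dimension is not 3N")
  BFAC_PREFACTOR * colSums(matrix(d, nrow = 3L))
}

#' Solve the full elastic model
#'
#' Convenience wrapper: Hessian, eigendecomposition, pseudo-inverse
#' covariance and B-factors in one call.
#'
#' @inheritParams build_hessian
#' @param n_skip low modes to skip in the pseudo-inverse (default 6).
#' @return Object of class `elastic_solution` with fields `hessian`,
#'   `values`, `vectors`, `covariance`, `bfactors`, `n`.
#' @export
solve_enm <- function(s, contacts = NULL, spec = interaction_spec(),
                      n_skip = 6L) {
  if (is.null(contacts)) contacts <- build_contacts(s, spec$cutoff_sq)
  H <- build_hessian(s, contacts, spec)
  sol <- decompose(H)
  M <- covariance_from_modes(sol, n_skip = n_skip)
  structure(
    list(hessian = H, values = sol$values, vectors = sol$vectors,
         covariance = M, bfactors = bfactors(M), n = s$n),
    class = "elastic_solution")
}

#' @export
print.elastic_solution <- function(x, ...) {
  nz <- sum(x$values < 1e-8 * max(x$values))
  cat(sprintf("Elastic solution: N = %d (%d modes, %d near-zero); B-factors in [%.4g, %.4g]\n",
              x$n, length(x$values), nz, min(x$bfactors), max(x$bfactors)))
  invisible(x)
}

#' Count near-zero (rigid-body) modes
#'
#' @param values ascending eigenvalues.
#' @param zero_tol relative threshold (default 1e-8 of the largest
#'   eigenvalue).
#' @return integer count of eigenvalues below `zero_tol * max(values)`.
#' @export
count_zero_modes <- function(values, zero_tol = 1e-8) {
  sum(values < zero_tol * max(values))
}
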