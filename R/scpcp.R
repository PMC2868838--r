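## Self-consistent pair contact probability (SCPCP) extension.
##
## Every non-covalent contact carries an occupancy probability p_ij in
## (0, 1]; the network's spring constants are kappa_ij * p_ij, the
## covariance is the pseudo-inverse of that weighted Hessian, and the
## probabilities are updated from the model's own fluctuations through a
## two-state Boltzmann rule until self-consistency:
##
##   p_ij  <-  1 / (1 + exp(-beta * kappa_ij + kappa_ij * g_ij / 2))
##
## where g_ij = tr(M_ii) + tr(M_jj) - 2 tr(M_ij) is the relative
## mean-square displacement of the pair read off the covariance blocks
## (per unit k_B T, since M is the Hessian pseudo-inverse; the physical
## fluctuation is g/beta, so the Boltzmann penalty beta * kappa * sigma^2/2
## reduces to kappa * g / 2).  The logistic form keeps probabilities in
## (0, 1) at every sweep by construction: the closed (energy -kappa_ij)
## and open (energy 0) states are weighted against the entropic cost of
## constraining a strongly fluctuating pair.  Large beta (cold, stable)
## drives p -> 1 and recovers the plain ANM; small beta lets weakened
## contacts inflate the fluctuations of their neighbours, the positive
## feedback that produces the finite-size unfolding transition.

## covariance of a probability-weighted network; generalized pseudo-inverse
## (all modes below zero_tol * lambda_max are skipped so a transiently
## disconnected model stays finite)
#' @noRd
scpcp_covariance <- function(s, contacts, spec, probs, zero_tol = 1e-8) {
  k <- pair_constants(s, contacts, spec)
  H <- hessian_from_pairs(s$coords,
                          rbind(contacts$covalent, contacts$noncovalent),
                          c(k$covalent, k$noncovalent * probs))
  sol <- decompose(H)
  nzero <- count_zero_modes(sol$values, zero_tol)
  M <- if (nzero == 6L) {
    covariance_from_modes(sol, n_skip = 6L, zero_tol = zero_tol)
  } else {
    suppressWarnings(covariance_from_modes(sol, n_skip = nzero,
                                           zero_tol = zero_tol))
  }
  list(M = M, n_zero = nzero, kappa = k$noncovalent)
}

## relative mean-square displacement per contact from covariance blocks
#' @noRd
pair_rmsf <- function(M, pairs) {
  d <- diag(M)
  tr_diag <- colSums(matrix(d, nrow = 3L))
  vapply(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    bi <- (3L * (i - 1L) + 1L):(3L * i)
    bj <- (3L * (j - 1L) + 1L):(3L * j)
    tr_diag[i] + tr_diag[j] - 2 * sum(diag(M[bi, bj, drop = FALSE]))
  }, numeric(1))
}

#' Solve the self-consistent pair contact probability model
#'
#' Damped fixed-point iteration: (a) build the Hessian with every
#' non-covalent spring scaled by its current occupancy probability; (b)
#' compute the covariance by pseudo-inversion; (c) update each probability
#' from the pair's relative mean-square displacement through the Boltzmann
#' occupancy rule (see the source header of this file); (d) mix old and new
#' probabilities with weight `damping`.  Iteration stops when the largest
#' absolute probability change falls below `tol` or after `max_iter`
#' sweeps.  A model that disconnects during iteration (more than six
#' vanishing modes) is flagged, not raised: it is the unfolding signal.
#'
#' @param s a [ca_structure()].
#' @param contacts a [build_contacts()] model (built from `spec$cutoff_sq`
#'   when `NULL`).
#' @param spec an [interaction_spec()].
#' @param beta inverse-temperature parameter (> 0); large values stabilize
#'   all contacts, small values melt them.
#' @param tol convergence bound on the maximum probability change
#'   (default 1e-6).
#' @param max_iter sweep limit (default 200).
#' @param damping mixing weight in (0, 1] for the new probabilities
#'   (default 0.5; conservative mixing avoids fixed-point oscillation).
#' @param init_probs optional start probabilities (default all 1).
#' @param freeze_probs if `TRUE`, no update sweeps are run: the state is the
#'   model evaluated at `init_probs` (used e.g. to recover the plain ANM at
#'   all-ones).
#' @return Object of class `scpcp_state`: `contact_probs`, `covariance`,
#'   `bfactors`, `beta`, `iterations`, `converged`, `residual`,
#'   `disconnected`, `mean_prob`, `contacts`.
#' @export
scpcp_solve <- function(s, contacts = NULL, spec = interaction_spec(),
                        beta = 1, tol = 1e-6, max_iter = 200L,
                        damping = 0.5, init_probs = NULL,
                        freeze_probs = FALSE) {
  stopifnot(inherits(s, "ca_structure"), inherits(spec, "interaction_spec"),
            beta > 0, damping > 0, damping <= 1)
  if (is.null(contacts)) contacts <- build_contacts(s, spec$cutoff_sq)
  nc <- contacts$noncovalent
  p <- if (is.null(init_probs)) rep(1, nrow(nc)) else as.numeric(init_probs)
  stopifnot(length(p) == nrow(nc), all(p >= 0 & p <= 1))
  iterations <- 0L
  residual <- Inf
  disconnected <- FALSE
  cv <- scpcp_covariance(s, contacts, spec, p)
  if (!freeze_probs) {
    for (it in seq_len(max_iter)) {
      g <- pair_rmsf(cv$M, nc)
      p_target <- stats::plogis(beta * cv$kappa - cv$kappa * g / 2)
      if (any(!is.finite(p_target)))
        stop("non-finite occupancy update; model parameters are pathological")
      p_new <- (1 - damping) * p + damping * p_target
      residual <- if (length(p) > 0L) max(abs(p_new - p)) else 0
      p <- p_new
      iterations <- it
      cv <- scpcp_covariance(s, contacts, spec, p)
      if (cv$n_zero > 6L) disconnected <- TRUE
      if (residual < tol) break
    }
  } else {
    residual <- 0
  }
  if (cv$n_zero > 6L) disconnected <- TRUE
  structure(
    list(contact_probs = p,
         covariance = cv$M,
         bfactors = bfactors(cv$M),
         beta = beta,
         iterations = iterations,
         converged = residual < tol,
         residual = residual,
         disconnected = disconnected,
         mean_prob = if (length(p) > 0L) mean(p) else NA_real_,
         contacts = contacts),
    class = "scpcp_state")
}

#' @export
print.scpcp_state <- function(x, ...) {
  cat(sprintf(paste0("SCPCP state: beta = %g, %d sweeps, %s (residual %.3g), ",
                     "mean contact probability %.4f%s\n"),
              x$beta, x$iterations,
              if (x$converged) "converged" else "not converged",
              x$residual, x$mean_prob,
              if (x$disconnected) " [disconnected]" else ""))
  invisible(x)
}

#' B-factors of an SCPCP state
#'
#' Applies the same diagonal block-trace formula as [bfactors()] to the
#' state's self-consistent covariance.
#'
#' @param state an `scpcp_state`.
#' @return numeric vector of length N.
#' @export
scpcp_bfactors <- function(state) {
  stopifnot(inherits(state, "scpcp_state"))
  bfactors(state$covariance)
}

#' Scan the SCPCP model over inverse temperatures
#'
#' Solves the model at each `beta`, warm-starting each point from the
#' previous converged probabilities (the first from all ones) so the scan
#' tracks one solution branch; with `warm_start = FALSE` every point is
#' solved independently from all-ones.  The mean contact probability per
#' beta is the order-parameter trace: scanned from stable (large beta)
#' toward unstable (small beta) it drops from near 1 in a sigmoidal,
#' finite-size-transition fashion.
#'
#' @inheritParams scpcp_solve
#' @param betas ordered vector of inverse temperatures.
#' @param warm_start chain starting probabilities along the scan?
#' @param ... passed to [scpcp_solve()] (`tol`, `max_iter`, `damping`).
#' @return list with `states` (one `scpcp_state` per beta) and `summary`
#'   (data frame `beta`, `mean_prob`, `converged`, `iterations`,
#'   `disconnected`).
#' @export
beta_scan <- function(s, contacts = NULL, spec = interaction_spec(),
                      betas, warm_start = TRUE, ...) {
  stopifnot(length(betas) >= 1L)
  if (is.null(contacts)) contacts <- build_contacts(s, spec$cutoff_sq)
  states <- vector("list", length(betas))
  p0 <- NULL
  for (k in seq_along(betas)) {
    states[[k]] <- scpcp_solve(s, contacts, spec, beta = betas[k],
                               init_probs = p0, ...)
    if (warm_start) p0 <- states[[k]]$contact_probs
  }
  list(states = states,
       summary = data.frame(
         beta = betas,
         mean_prob = vapply(states, `[[`, numeric(1), "mean_prob"),
         converged = vapply(states, `[[`, logical(1), "converged"),
         iterations = vapply(states, `[[`, integer(1), "iterations"),
         disconnected = vapply(states, `[[`, logical(1), "disconnected")))
}
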