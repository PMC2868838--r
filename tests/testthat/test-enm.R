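# Hessian assembly, eigenmodes, pseudo-inverse covariance, B-factors

test_that("two beads joined by one spring follow the closed form", {
  K <- default_spec$alpha
  s <- ca_structure(rbind(c(0, 0, 0), c(3.8, 0, 0)), c("A", "A"), c("A", "G"))
  cm <- build_contacts(s)
  H <- build_hessian(s, cm, default_spec)
  expect_equal(H, t(H))
  e <- decompose(H)
  # one nonzero eigenvalue 2K, five zero modes
  expect_equal(e$values[6], 2 * K)
  expect_equal(e$values[1:5], rep(0, 5), tolerance = 1e-12 * K)
  M <- covariance_from_modes(e, n_skip = 5)
  expect_equal(max(eigen(M, symmetric = TRUE)$values), 1 / (2 * K))
  # mirror-symmetric system: equal B-factors
  b <- bfactors(M)
  expect_equal(b[1], b[2])
})

test_that("Hessian rows sum to zero blockwise and the spectrum has six zero modes", {
  s <- toy_helix(5)
  cm <- build_contacts(s)
  H <- build_hessian(s, cm, default_spec)
  expect_equal(H, t(H))
  # translation invariance: each 3x3 block row sums to zero
  n <- s$n
  for (i in 1:n) {
    bi <- (3 * (i - 1) + 1):(3 * i)
    acc <- matrix(0, 3, 3)
    for (j in 1:n) acc <- acc + H[bi, (3 * (j - 1) + 1):(3 * j)]
    expect_equal(acc, matrix(0, 3, 3), tolerance = 1e-10)
  }
  e <- decompose(H)
  expect_equal(count_zero_modes(e$values), 6L)
  # spectral reconstruction
  expect_equal(e$vectors %*% (e$values * t(e$vectors)), H, tolerance = 1e-8)
  # coincident beads are refused with the pair named
  s_bad <- ca_structure(rbind(c(0, 0, 0), c(0, 0, 0), c(3.8, 0, 0)),
                        rep("A", 3), c("A", "C", "D"))
  expect_error(build_hessian(s_bad, build_contacts(s_bad), default_spec),
               "coincident")
})

test_that("a straight chain is mechanically degenerate (collinear springs)", {
  # all spring directions along x: only axial modes cost energy, so the
  # zero-mode count is 3N - (N - 1), not 6 -- the reason elastic-model
  # fixtures use the helix/ring/globule topologies
  s <- make_structure(toy_spec("chain", 5))$structure
  e <- decompose(build_hessian(s, build_contacts(s), default_spec))
  expect_equal(count_zero_modes(e$values), 11L)
})

test_that("decompose validates symmetry and orders eigenvalues ascending", {
  A <- matrix(rnorm(36), 6)
  expect_error(decompose(A), "symmetric")
  Sy <- crossprod(A)
  e <- decompose(Sy)
  expect_false(is.unsorted(e$values))
  expect_equal(crossprod(e$vectors), diag(6), tolerance = 1e-10)
})

test_that("pseudo-inverse identities hold and agree with a generic routine", {
  skip_if_not_installed("MASS")
  for (seed in 1:5) {
    s <- toy_globule(10, seed = seed)
    H <- build_hessian(s, build_contacts(s), default_spec)
    e <- decompose(H)
    expect_equal(count_zero_modes(e$values), 6L)
    M <- covariance_from_modes(e)
    expect_equal(qr(M, tol = 1e-10)$rank, 3 * s$n - 6)
    relerr <- function(a, b) max(abs(a - b)) / max(abs(b))
    expect_lt(relerr(M %*% H %*% M, M), 1e-8)
    expect_lt(relerr(H %*% M %*% H, H), 1e-8)
    # independent oracle: generic Moore-Penrose pseudo-inverse
    expect_lt(relerr(M, MASS::ginv(H)), 1e-6)
  }
})

test_that("covariance_from_modes flags suspicious skipped modes and short input", {
  s <- toy_globule(8, seed = 2)
  e <- decompose(build_hessian(s, build_contacts(s), default_spec))
  expect_silent(covariance_from_modes(e))
  # skipping a genuinely nonzero mode warns (pre-stressed/disconnected signal)
  expect_warning(covariance_from_modes(e, n_skip = 7L), "disconnected")
  expect_error(covariance_from_modes(list(values = 1:3, vectors = diag(3))),
               "modes")
})

test_that("B-factors equal the brute-force block traces and respect symmetry", {
  s <- toy_globule(5, seed = 4)
  sol <- solve_enm(s)
  # direct summation oracle
  expect_equal(sol$bfactors,
               sapply(1:s$n, function(i) {
                 bi <- (3 * (i - 1) + 1):(3 * i)
                 (8 * pi^2 / 3) * sum(diag(sol$covariance[bi, bi]))
               }))
  expect_true(all(sol$bfactors >= 0))
  # identity covariance: all B equal
  expect_equal(bfactors(diag(9)), rep(8 * pi^2, 3))
  # uniform puckered ring with uniform springs: constant profile by the
  # dihedral symmetry of the bead graph (the ring-closing pair is
  # non-covalent, so uniformity requires equal covalent/contact strengths;
  # exact coordinates, since PDB-rounded ones break the symmetry slightly)
  r <- 3.8 / (2 * sin(pi / 8)); th <- 2 * pi * (0:7) / 8
  ring <- ca_structure(cbind(r * cos(th), r * sin(th),
                             0.5 * rep(c(-1, 1), 4)),
                       rep("A", 8), rep("A", 8))
  uni <- load_interaction_tables("MJ"); uni[] <- 82
  spec_uni <- interaction_spec(alpha = 82, intra_table = uni, inter_table = uni)
  bb <- solve_enm(ring, spec = spec_uni)$bfactors
  expect_equal(max(bb) - min(bb), 0, tolerance = 1e-8 * max(bb))
})

test_that("rigid motion and global spring scaling act as expected on the model", {
  s <- toy_globule(9, seed = 6)
  cm <- build_contacts(s)
  sol <- solve_enm(s, cm, default_spec)
  for (seed in 1:2) {
    moved <- ca_structure(random_rigid(s$coords, seed), s$chain_ids,
                          s$residue_names)
    sol_m <- solve_enm(moved, build_contacts(moved), default_spec)
    expect_equal(sol_m$values, sol$values, tolerance = 1e-7)
    expect_equal(sol_m$bfactors, sol$bfactors, tolerance = 1e-6)
  }
  # scaling every spring by c scales eigenvalues by c and B-factors by 1/c
  c_scale <- 3.5
  mj <- load_interaction_tables("MJ")
  spec_sc <- interaction_spec(alpha = default_spec$alpha * c_scale,
                              intra_table = mj * c_scale,
                              inter_table = mj * c_scale)
  spec_ref <- interaction_spec(intra_table = mj, inter_table = mj)
  sol_ref <- solve_enm(s, cm, spec_ref)
  sol_sc <- solve_enm(s, cm, spec_sc)
  expect_equal(sol_sc$values, c_scale * sol_ref$values, tolerance = 1e-9)
  expect_equal(sol_sc$bfactors, sol_ref$bfactors / c_scale, tolerance = 1e-9)
})
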