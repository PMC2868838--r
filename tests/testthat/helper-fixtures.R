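# shared fixtures: built fresh in code, no files on disk

default_spec <- interaction_spec()

toy_globule <- function(n = 30L, seed = 7L, sequence_model = "random") {
  make_structure(toy_spec("globule", n, seed = seed,
                          sequence_model = sequence_model))$structure
}

toy_helix <- function(n = 8L, seed = 1L) {
  make_structure(toy_spec("helix", n, seed = seed,
                          sequence_model = "random"))$structure
}

# independent brute-force MI for two character columns (direct double sum
# over observed symbols; log base 2)
brute_mi <- function(ci, cj) {
  S <- length(ci)
  tot <- 0
  for (x in unique(ci)) for (y in unique(cj)) {
    pxy <- sum(ci == x & cj == y) / S
    if (pxy > 0) tot <- tot + pxy * log2(pxy / ((sum(ci == x) / S) * (sum(cj == y) / S)))
  }
  tot
}

# random rigid-body transform of an N x 3 coordinate matrix
random_rigid <- function(coords, seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t(R %*% t(coords)) + matrix(rnorm(3, sd = 10), nrow(coords), 3, byrow = TRUE)
}
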