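# contact breaking, mutation, Frobenius norms, batch protocol, quadrants

test_that("break_contact removes exactly one pair and validates its input", {
  s <- toy_globule(12, seed = 5)
  cm <- build_contacts(s)
  k <- nrow(cm$noncovalent)
  pair <- cm$noncovalent[3, ]
  cm2 <- break_contact(cm, pair)
  expect_equal(nrow(cm2$noncovalent), k - 1L)
  expect_equal(nrow(cm$noncovalent), k)  # input untouched
  expect_false(any(cm2$noncovalent[, 1] == pair[1] &
                   cm2$noncovalent[, 2] == pair[2]))
  # covalent pairs cannot be broken; absent pairs are refused by name
  expect_error(break_contact(cm, cm$covalent[1, ]), "covalent")
  expect_error(break_contact(cm, c(1, 1200)), "not a non-covalent")
  # the chain stays connected: still exactly 6 zero modes after a break
  e <- decompose(build_hessian(s, cm2, default_spec))
  expect_equal(count_zero_modes(e$values), 6L)
})

test_that("mutation changes only the residue identity and its Hessian blocks", {
  s <- toy_globule(10, seed = 8)
  cm <- build_contacts(s)
  pos <- 4L
  mut <- mutate_sequence(s, pos, "W")
  expect_equal(mut$coords, s$coords)
  expect_equal(mut$residue_names[-pos], s$residue_names[-pos])
  expect_equal(mut$residue_names[pos], "W")
  expect_error(mutate_sequence(s, 2, "B"), "invalid residue")
  # only blocks involving the mutated site differ: its own row/column and
  # the diagonal blocks of its contact partners (their row sums change)
  H_wt <- build_hessian(s, cm, default_spec)
  H_mut <- build_hessian(mut, cm, default_spec)
  delta <- abs(H_wt - H_mut)
  blk <- function(i) (3 * (i - 1) + 1):(3 * i)
  partners <- unique(c(
    cm$noncovalent[cm$noncovalent[, 1] == pos, 2],
    cm$noncovalent[cm$noncovalent[, 2] == pos, 1]))
  delta[blk(pos), ] <- 0
  delta[, blk(pos)] <- 0
  for (p in partners) delta[blk(p), blk(p)] <- 0
  expect_equal(max(delta), 0)
  # mutating a residue to itself is a no-op downstream
  same <- mutate_sequence(s, pos, s$residue_names[pos])
  expect_equal(frobenius_norm(solve_enm(s, cm)$covariance,
                              solve_enm(same, cm)$covariance), 0)
  # mutation FN against an independent full-pipeline recomputation
  f <- frobenius_norm(solve_enm(s, cm)$covariance,
                      solve_enm(mut, cm)$covariance)
  oracle <- sqrt(sum((solve_enm(s, cm)$covariance -
                        solve_enm(mut, cm)$covariance)^2))
  expect_equal(f, oracle)
  expect_gt(f, 0)
})

test_that("frobenius_norm matches elementwise oracles, with and without subsets", {
  set.seed(3)
  m1 <- matrix(rnorm(144), 12)
  m2 <- matrix(rnorm(144), 12)
  expect_equal(frobenius_norm(m1, m1), 0)
  d <- 0.37
  m3 <- m1; m3[5, 7] <- m1[5, 7] + d
  expect_equal(frobenius_norm(m1, m3), d)
  expect_error(frobenius_norm(m1, matrix(0, 3, 3)), "shape")
  # subset {1, 3} of a 4-residue (12x12) pair: brute-force over the 4 blocks
  sub <- c(1L, 3L)
  acc <- 0
  for (i in sub) for (j in sub) {
    bi <- (3 * (i - 1) + 1):(3 * i); bj <- (3 * (j - 1) + 1):(3 * j)
    acc <- acc + sum((m1[bi, bj] - m2[bi, bj])^2)
  }
  expect_equal(frobenius_norm(m1, m2, subset = sub), sqrt(acc))
  # subset = all residues equals the full norm
  expect_equal(frobenius_norm(m1, m2, subset = 1:4), frobenius_norm(m1, m2))
  # metric properties on random triples
  m4 <- matrix(rnorm(144), 12)
  expect_equal(frobenius_norm(m1, m2), frobenius_norm(m2, m1))
  expect_lte(frobenius_norm(m1, m4),
             frobenius_norm(m1, m2) + frobenius_norm(m2, m4) + 1e-12)
})

test_that("breaking a contact with a negligible spring constant has no effect", {
  # make exactly one contact's spring constant negligible (pair A-C) while
  # the rest of the network keeps full strength and stays well-conditioned
  s <- toy_globule(10, seed = 12)
  cm <- build_contacts(s)
  target <- cm$noncovalent[nrow(cm$noncovalent), ]
  s$residue_names <- rep("G", s$n)
  s$residue_names[target[1]] <- "A"
  s$residue_names[target[2]] <- "C"
  soft <- load_interaction_tables("MJ")
  soft["A", "C"] <- soft["C", "A"] <- 1e-9
  spec_soft <- interaction_spec(intra_table = soft, inter_table = soft)
  wt <- solve_enm(s, cm, spec_soft)
  mut <- solve_enm(s, break_contact(cm, target), spec_soft)
  f_soft <- frobenius_norm(wt$covariance, mut$covariance)
  expect_lt(f_soft, 1e-6)
  # the same break at full strength has a real effect, orders above
  wt_full <- solve_enm(s, cm, default_spec)
  mut_full <- solve_enm(s, break_contact(cm, target), default_spec)
  expect_gt(frobenius_norm(wt_full$covariance, mut_full$covariance),
            1e3 * f_soft)
})

test_that("the batch protocol is worker-invariant and equals the sequential oracle", {
  s <- toy_globule(18, seed = 9)
  cm <- build_contacts(s)
  pairs <- cm$noncovalent[unique(round(seq(1, nrow(cm$noncovalent),
                                           length.out = 6))), ]
  runs <- lapply(c(1L, 2L, 4L), function(w)
    as.data.frame(run_break_protocol(s, default_spec, pairs, contacts = cm,
                                     workers = w)))
  expect_identical(runs[[1]], runs[[2]])
  expect_identical(runs[[1]], runs[[3]])
  # sequential composition oracle
  wt <- solve_enm(s, cm, default_spec)
  for (r in seq_len(nrow(pairs))) {
    f <- frobenius_norm(wt$covariance,
                        solve_enm(s, break_contact(cm, pairs[r, ]),
                                  default_spec)$covariance)
    expect_equal(runs[[1]]$fnorm[r], f)
  }
  # fail-fast validation and flag behavior
  expect_error(run_break_protocol(s, default_spec, rbind(pairs, c(1L, 2L))),
               "non-covalent")
  no_f <- run_break_protocol(s, default_spec, pairs[1:2, ], contacts = cm,
                             compute_fnorm = FALSE)
  expect_true(all(is.na(as.data.frame(no_f)$fnorm)))
  with_b <- run_break_protocol(s, default_spec, pairs[1:2, ], contacts = cm,
                               write_bfactors = TRUE)
  expect_length(with_b[[1]]$bfactors, s$n)
})

test_that("top-MI contact selection ranks and tie-breaks deterministically", {
  s <- toy_globule(15, seed = 10)
  cm <- build_contacts(s)
  a <- make_alignment(15, 80, seed = 3)
  mi <- mutual_information(a)
  expect_equal(nrow(select_top_mi_contacts(mi, cm, 0)), 0L)
  sel <- select_top_mi_contacts(mi, cm, 5)
  # brute-force sort oracle
  nc <- cm$noncovalent
  vals <- mi$mi[nc]
  o <- order(-vals, nc[, 1], nc[, 2])[1:5]
  expect_equal(unname(sel[, "i"]), nc[o, 1])
  expect_equal(unname(sel[, "j"]), nc[o, 2])
  expect_equal(unname(sel[, "mi"]), vals[o])
  # all-equal MI: lexicographically first contacts win
  mi_flat <- mi; mi_flat$mi[] <- 1
  sel_f <- select_top_mi_contacts(mi_flat, cm, 4)
  lex <- nc[order(nc[, 1], nc[, 2]), ][1:4, ]
  expect_equal(unname(sel_f[, 1:2]), unname(lex))
  # n beyond the contact count returns everything with a warning
  expect_warning(all_c <- select_top_mi_contacts(mi, cm, 10 * nrow(nc)),
                 "returning all")
  expect_equal(nrow(all_c), nrow(nc))
})

test_that("quadrant annotation matches the brute-force nearest-corner rule", {
  s <- toy_globule(16, seed = 13)
  cm <- build_contacts(s)
  a <- make_alignment(16, 60, seed = 5)
  mi <- mutual_information(a)
  pairs <- cm$noncovalent[unique(round(seq(1, nrow(cm$noncovalent),
                                           length.out = 8))), ]
  recs <- run_break_protocol(s, default_spec, pairs, contacts = cm)
  ann <- annotate_quadrants(recs, mi)
  # independent exhaustive assignment
  x <- (ann$mi - min(ann$mi)) / diff(range(ann$mi))
  y <- (ann$fnorm - min(ann$fnorm)) / diff(range(ann$fnorm))
  corners <- list("45" = c(1, 1), "135" = c(0, 1), "225" = c(0, 0), "315" = c(1, 0))
  for (k in seq_along(x)) {
    d <- vapply(corners, function(cc) (x[k] - cc[1])^2 + (y[k] - cc[2])^2,
                numeric(1))
    expect_equal(as.character(ann$quadrant[k]),
                 names(which.min(d)))  # no exact ties in this random batch
  }
  # extremes land in their named corners
  expect_equal(as.character(ann$quadrant[which(x > 0.99 & y > 0.99)]),
               rep("45", sum(x > 0.99 & y > 0.99)))
  one <- run_break_protocol(s, default_spec, pairs[1, , drop = FALSE],
                            contacts = cm)
  expect_error(annotate_quadrants(one, mi), "at least two")
})

test_that("the end-to-end protocol recovers a planted coevolving contact", {
  s <- toy_globule(20, seed = 21)
  cm <- build_contacts(s)
  planted <- cm$noncovalent[17, ]
  a <- make_alignment(20, 300, covarying = rbind(planted), coupling = 1,
                      seed = 2)
  res <- simc(s, a, top = 10, workers = 1)
  tab <- res$table
  # the planted pair has the highest MI in the batch and is present
  expect_equal(unname(unlist(tab[which.max(tab$mi), c("i", "j")])),
               unname(planted))
  expect_true(all(c("45", "135", "225", "315") %in% levels(tab$quadrant)))
  expect_equal(nrow(tab), 10L)
})
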