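test_that("decay follows (1 - dist/3)^2 inside the depth-2 neighborhood", {
  prop <- tiny_mols()$propane
  expect_equal(decay(prop, 1, 1), 1)
  expect_equal(decay(prop, 1, 2), 4 / 9)
  expect_equal(decay(prop, 1, 3), 1 / 9)
  benz <- tiny_mols()$benzene
  expect_error(decay(benz, 1, 4), "depth-2")   # distance 3
})

test_that("atom similarity is 1 for identical environments, closed-form for isolated atoms", {
  m <- tiny_mols()
  prop <- m$propane
  expect_equal(atom_similarity(prop, 1, prop, 1), 1)
  expect_equal(atom_similarity(prop, 1, prop, 3), 1)   # symmetric terminals
  S <- pairwise_matrix(prop, prop)
  expect_equal(diag(S), rep(1, 3))

  # isolated atoms: no neighbor term, similarity is the bare RBF
  meth <- m$methane; amm <- m$ammonia
  expect_equal(atom_similarity(meth, 1, meth, 1), 1)
  delta2 <- sum((meth$A[1, ] - amm$A[1, ])^2)
  g <- meth$config$gamma_atom
  expect_equal(atom_similarity(meth, 1, amm, 1), exp(-g * delta2),
               tolerance = 1e-12)
})

test_that("atom similarity agrees with an independent reference recursion", {
  m <- tiny_mols()
  eth <- m$ethanol; prop <- m$propane
  got <- atom_similarity(eth, 1, prop, 1)
  want <- ref_atom_similarity(eth, 1, prop, 1)
  expect_equal(got, want, tolerance = 1e-10)
  expect_gt(got, 0); expect_lt(got, 1)
  # spot-check several atom pairs across molecules
  pool <- mol_pool()
  set.seed(42)
  for (k in 1:10) {
    A <- pool[[sample(length(pool), 1)]]
    B <- pool[[sample(length(pool), 1)]]
    i <- sample(A$n, 1); j <- sample(B$n, 1)
    expect_equal(atom_similarity(A, i, B, j),
                 ref_atom_similarity(A, i, B, j), tolerance = 1e-10,
                 info = paste(A$id, i, B$id, j))
  }
})

test_that("pairwise matrices are symmetric in molecule order with entries in [0,1]", {
  m <- tiny_mols()
  S1 <- pairwise_matrix(m$ethanol, m$acetone)
  S2 <- pairwise_matrix(m$acetone, m$ethanol)
  expect_equal(dim(S1), c(3L, 4L))
  expect_equal(S1, t(S2), tolerance = 1e-12)
  expect_true(all(S1 >= 0 & S1 <= 1))
  expect_error(pairwise_matrix(m$ethanol,
                               compute_descriptors(m$propane,
                                 within(default_descriptor_config(),
                                        atom <- atom[1:3]))),
               "mismatch")
})

test_that("Hungarian assignment solves worked examples", {
  oa <- optimal_assignment(diag(3))
  expect_equal(oa$score, 3)
  expect_equal(oa$mapping, 1:3)
  oa2 <- optimal_assignment(matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2))
  expect_equal(oa2$score, 1.1)
  expect_equal(oa2$mapping, c(1L, 2L))
})

test_that("Hungarian assignment equals the brute-force permutation maximum", {
  set.seed(1)
  for (trial in 1:200) {
    nr <- sample(7, 1); nc <- sample(7, 1)
    S <- matrix(runif(nr * nc), nr, nc)
    expect_equal(optimal_assignment(S)$score, bf_assignment_max(S),
                 tolerance = 1e-9)
  }
})

test_that("normalized similarity is 1 on the diagonal, symmetric, in (0,1)", {
  m <- tiny_mols()
  expect_equal(normalized_similarity(m$ethanol, m$ethanol), 1)
  s <- normalized_similarity(m$ethanol, m$propane)
  expect_equal(s, normalized_similarity(m$propane, m$ethanol))
  expect_gt(s, 0); expect_lt(s, 1)
  # independent recomputation of the normalization
  raw <- optimal_assignment(pairwise_matrix(m$ethanol, m$propane))$score
  expect_equal(s, raw / sqrt(3 * 3))
  # randomized suite: all normalized scores in [0, 1]
  pool <- mol_pool()
  set.seed(3)
  for (k in 1:20) {
    A <- pool[[sample(length(pool), 1)]]; B <- pool[[sample(length(pool), 1)]]
    v <- normalized_similarity(A, B)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("normalize_weights maps the bounded box onto the constraint set", {
  expect_equal(as.numeric(normalize_weights(rep(0, 5))), rep(1, 5))
  expect_equal(as.numeric(normalize_weights(c(0.5, -0.5))), c(2, 0))
  expect_equal(as.numeric(normalize_weights(rep(-0.5, 4))), rep(1, 4))
  expect_error(normalize_weights(numeric(0)), "empty")
  set.seed(5)
  for (k in 1:200) {
    m <- sample(1:30, 1)
    w <- normalize_weights(runif(m, -0.5, 0.5))
    expect_true(all(w >= 0))
    expect_equal(sum(w), m, tolerance = 1e-9)
  }
})

test_that("uniform weights reproduce the unweighted assignment bit-for-bit", {
  m <- tiny_mols()
  S <- pairwise_matrix(m$acetone, m$ethanol)
  un <- optimal_assignment(S)
  w <- normalize_weights(rep(0, 4))
  we <- weighted_similarity(m$acetone, m$ethanol, w, S = S)
  expect_identical(we$mapping, un$mapping)
  expect_equal(we$score, un$score, tolerance = 1e-12)
  expect_equal(we$normalized, un$score / sqrt(4 * 3), tolerance = 1e-12)
})

test_that("weight concentration and zero-weight atoms behave per the objective", {
  m <- tiny_mols()
  Q <- m$acetone; B <- m$ethanol
  S <- pairwise_matrix(Q, B)
  w <- structure(c(4, 0, 0, 0), class = "oa_weights")
  we <- weighted_similarity(Q, B, w, S = S)
  expect_equal(we$score, 4 * max(S[1, ]), tolerance = 1e-12)
  # perturbing a zero-weight atom's descriptors leaves the raw score unchanged
  S2 <- S; S2[2, ] <- runif(ncol(S))
  expect_equal(weighted_similarity(Q, B, w, S = S2)$score, we$score,
               tolerance = 1e-12)
  expect_error(weighted_similarity(Q, B, structure(c(1, 1, 1), class = "oa_weights")),
               "mismatch")
})

test_that("raising one weight never lowers the optimal raw score (fixed S)", {
  set.seed(11)
  for (k in 1:50) {
    S <- matrix(runif(20), 4, 5)
    w <- runif(4, 0, 2)
    base <- optimal_assignment(w * S)$score
    i <- sample(4, 1)
    w2 <- w; w2[i] <- w2[i] + runif(1, 0, 1)
    expect_gte(optimal_assignment(w2 * S)$score, base - 1e-12)
  }
})

test_that("weight files round-trip with header metadata", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  w <- normalize_weights(runif(7, -0.5, 0.5))
  write_weights(w, tmp, query_id = "q1")
  back <- read_weights(tmp)
  expect_equal(as.numeric(back), as.numeric(w), tolerance = 1e-12)
  expect_equal(attr(back, "query_id"), "q1")
})
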