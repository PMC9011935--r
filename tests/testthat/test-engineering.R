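test_that("first_pc_scores matches the covariance eigendecomposition oracle", {
  # the spec-style 3 x 2 example plus random small matrices
  m <- matrix(c(1, 0, 1, 0, 1, 1), nrow = 3, byrow = FALSE)
  expect_equal_up_to_sign(first_pc_scores(m), oracle_pc1_scores(m), 1e-9)
  for (seed in 1:25) {
    set.seed(seed)
    r <- sample(2:20, 1); c <- sample(2:10, 1)
    x <- matrix(rnorm(r * c), r)
    expect_equal_up_to_sign(first_pc_scores(x), oracle_pc1_scores(x), 1e-9)
  }
})

test_that("first_pc_scores sign convention: largest-|loading| entry positive", {
  set.seed(3)
  x <- matrix(rnorm(30), 10)
  s1 <- first_pc_scores(x)
  s2 <- first_pc_scores(x[, c(2, 1, 3)])  # column order must not flip sign
  expect_equal(sort(abs(s1)), sort(abs(s2)), tolerance = 1e-9)
})

test_that("first_pc_scores degenerate cases follow documented conventions", {
  # all-equal columns: no variance -> zero vector
  expect_identical(first_pc_scores(matrix(2, 4, 3)), numeric(4))
  # single column: centering only
  expect_equal(first_pc_scores(matrix(c(1, 3, 5), ncol = 1)), c(-2, 0, 2))
  # empty matrix: degenerate signal, no exception
  out <- first_pc_scores(matrix(numeric(0), nrow = 0, ncol = 0))
  expect_length(out, 0)
  expect_true(isTRUE(attr(out, "degenerate")))
})

test_that("aggregate_local yields a constant 157-length vector", {
  fx <- fixture_smiles(30, seed = 9)
  mols <- parse_molecules(fx, canonicalize = FALSE)
  sizes <- vapply(mols, `[[`, integer(1), "n_atoms")
  expect_gt(max(sizes), 5)  # the set spans small and larger molecules
  for (m in mols) {
    v <- aggregate_local(featurize_atoms(m), featurize_bonds(m))
    expect_length(v, 157L)
    expect_true(all(is.finite(v)))
  }
})

test_that("bond-free molecules contribute zeros; atom part matches PCA oracle", {
  w <- parse_smiles("O", canonicalize = FALSE)
  v <- aggregate_local(featurize_atoms(w), featurize_bonds(w))
  expect_identical(unname(unclass(v)[146:157]), rep(0, 12))
  eth <- parse_smiles("CCO", canonicalize = FALSE)
  fa <- featurize_atoms(eth)
  v <- aggregate_local(fa, featurize_bonds(eth))
  expect_equal_up_to_sign(unname(unclass(v)[1:145]),
                          oracle_pc1_scores(t(fa$values)), 1e-9)
})

test_that("dataset PCA recovers planted low-rank structure", {
  set.seed(11)
  loadings <- matrix(rnorm(3 * 157), 3)
  scores <- matrix(rnorm(100 * 3), 100)
  x <- scores %*% loadings
  red <- reduce_local_dataset(x, 50L)
  evr <- attr(red, "explained_variance_ratio")
  expect_equal(sum(evr[1:3]), 1, tolerance = 1e-9)
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-9)
})

test_that("full-rank PCA reconstructs the centered matrix", {
  set.seed(12)
  x <- matrix(rnorm(40 * 8), 40)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  recon <- pc$x %*% t(pc$rotation)
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(recon, centered, tolerance = 1e-8, ignore_attr = TRUE)
  # and our reduction at full n_components carries the same scores
  red <- reduce_local_dataset(x, 8L)
  expect_equal(unname(red[, 1:8]), unname(pc$x[, 1:8]), tolerance = 1e-8)
})

test_that("row permutation of molecules permutes PCA scores identically", {
  set.seed(13)
  x <- matrix(rnorm(60 * 10), 60)
  perm <- sample(60)
  r1 <- reduce_local_dataset(x, 5L)
  r2 <- reduce_local_dataset(x[perm, ], 5L)
  # align the per-component sign (arbitrary in PCA) before comparing
  for (j in seq_len(ncol(r2))) {
    if (sign(r2[1, j]) != sign(r1[perm[1], j])) r2[, j] <- -r2[, j]
  }
  expect_equal(unname(r1[perm, ]), unname(r2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("reduce_local_dataset refuses more components than molecules", {
  expect_error(reduce_local_dataset(matrix(rnorm(20), 4), 10L),
               "smaller n_components")
})

test_that("z-scoring uses the population SD and flags constants", {
  z <- zscore_columns(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(z[, "a"], c(-1.2247, 0, 1.2247), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_identical(unname(z[, "b"]), c(0, 0, 0))
  expect_identical(unname(attr(z, "constant")), c(FALSE, TRUE))
  set.seed(14)
  big <- zscore_columns(matrix(rnorm(200 * 5), 200))
  expect_true(all(abs(colMeans(big)) < 1e-10))
  expect_true(all(abs(sqrt(colMeans(big^2)) - 1) < 1e-10))
})

test_that("assemble_feature_table drops exactly the zero-variance columns", {
  set.seed(15)
  local <- matrix(rnorm(30 * 5), 30,
                  dimnames = list(NULL, paste("PCA", 1:5)))
  global <- matrix(rnorm(30 * 4), 30,
                   dimnames = list(NULL, paste0("d", 1:4)))
  ft <- assemble_feature_table(local, zscore_columns(global))
  expect_identical(ncol(ft$values), 9L)
  expect_length(ft$dropped, 0)
  # inject a constant column: it is flagged, zeroed, and dropped
  global2 <- cbind(global, dconst = 7)
  ft2 <- assemble_feature_table(local, zscore_columns(global2))
  expect_identical(ft2$dropped, "dconst")
  expect_identical(ncol(ft2$values), 9L)
  # the dropped set does not depend on molecule order
  perm <- sample(30)
  ft3 <- assemble_feature_table(local[perm, ],
                                zscore_columns(global2[perm, ]))
  expect_identical(ft3$dropped, ft2$dropped)
  expect_error(assemble_feature_table(local[1:10, ], zscore_columns(global)),
               "disagree")
})

test_that("the engineering pipeline is deterministic end to end", {
  fx <- fixture_smiles(25, seed = 21)
  mols <- parse_molecules(fx, canonicalize = FALSE)
  ft1 <- suppressWarnings(suppressMessages(
    engineer_features(mols, n_components = 10L)))
  ft2 <- suppressWarnings(suppressMessages(
    engineer_features(mols, n_components = 10L)))
  expect_identical(ft1$values, ft2$values)
  expect_identical(ft1$provenance[1:10], rep("local", 10))
  md <- attr(ft1, "metadata")
  expect_identical(md$d_g, length(md$descriptor_set))
})
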