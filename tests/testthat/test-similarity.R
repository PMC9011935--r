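fake_fp <- function(bits, counts = rep(1L, length(bits)), kind = "binary") {
  structure(list(id = "fake", kind = kind, radius = 1L, n_bits = 2048L,
                 bits = bits, counts = counts, features = list()),
            class = "ecfp")
}

test_that("tanimoto set arithmetic: identity, disjoint, half overlap", {
  a <- fake_fp(c(1, 2, 3))
  b <- fake_fp(c(2, 3, 4))
  expect_identical(tanimoto(a, a), 1)
  expect_identical(tanimoto(a, fake_fp(c(7, 8))), 0)
  expect_identical(tanimoto(a, b), 0.5)  # |{2,3}| / |{1,2,3,4}|
  # count generalization: sum(min) / sum(max)
  ca <- fake_fp(c(1, 2), counts = c(3L, 1L), kind = "count")
  cb <- fake_fp(c(1, 2), counts = c(1L, 2L), kind = "count")
  expect_equal(tanimoto(ca, cb), (1 + 1) / (3 + 2))
  expect_error(tanimoto(a, ca), "mismatched")
  expect_warning(z <- tanimoto(fake_fp(numeric(0)), fake_fp(numeric(0))),
                 "empty")
  expect_identical(z, 0)
})

test_that("ecfp: determinism, sparsity, radius-0 behaviour", {
  b1 <- ecfp(parse_smiles("c1ccccc1", canonicalize = FALSE))
  b2 <- ecfp(parse_smiles("c1ccccc1", canonicalize = FALSE))
  expect_identical(b1$bits, b2$bits)
  expect_identical(b1$counts, b2$counts)
  expect_gte(length(b1$bits), 1)
  expect_lt(length(b1$bits), 100)  # far sparser than 2048
  # radius 0: bits depend only on the atoms, not their arrangement
  f1 <- ecfp(parse_smiles("CCO", canonicalize = FALSE), radius = 0)
  f2 <- ecfp(parse_smiles("OCC", canonicalize = FALSE), radius = 0)
  expect_identical(sort(f1$bits), sort(f2$bits))
  f3 <- ecfp(parse_smiles("CCN", canonicalize = FALSE), radius = 0)
  expect_false(identical(sort(f1$bits), sort(f3$bits)))
})

test_that("tanimoto matrix is symmetric with a unit diagonal", {
  mols <- parse_molecules(data.frame(
    id = c("a", "b", "c", "c2"),
    smiles = c("c1ccccc1", "CCO", "CC(=O)O", "CC(=O)O")),
    canonicalize = FALSE)
  tm <- tanimoto_matrix(mols)
  expect_identical(unname(diag(tm)), rep(1, 4))
  expect_identical(tm, t(tm))
  # duplicate molecules produce identical rows
  expect_identical(unname(tm["c", ]), unname(tm["c2", ]))
  expect_identical(tm["c", "c2"], 1)
})

test_that("similarity-map weights match the brute-force bit-removal oracle", {
  ref <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O", "ref", canonicalize = FALSE)
  test <- parse_smiles("CC(=O)Oc1ccc(Cl)cc1", "test", canonicalize = FALSE)
  sm <- similarity_map_weights(ref, test, normalize = FALSE)
  # oracle: recompute each weight from the definition using raw features
  fp_ref <- ecfp(ref, 2, 2048, counted = TRUE)
  fp_test <- ecfp(test, 2, 2048, counted = TRUE)
  count_vec <- function(feats) {
    v <- table(vapply(feats, `[[`, numeric(1), "bit"))
    list(bits = as.numeric(names(v)), counts = as.integer(v))
  }
  tani <- function(x, y) {
    all_bits <- union(x$bits, y$bits)
    cx <- cy <- numeric(length(all_bits))
    cx[match(x$bits, all_bits)] <- x$counts
    cy[match(y$bits, all_bits)] <- y$counts
    sum(pmin(cx, cy)) / sum(pmax(cx, cy))
  }
  base <- tani(count_vec(fp_ref$features), count_vec(fp_test$features))
  for (atom in seq_len(test$n_atoms)) {
    kept <- Filter(function(f) !(atom %in% f$atoms), fp_test$features)
    sim_rm <- if (length(kept) == 0) 0
              else tani(count_vec(fp_ref$features), count_vec(kept))
    expect_equal(sm$raw_weights[atom], base - sim_rm, tolerance = 1e-12)
  }
})

test_that("similarity-map sign conventions", {
  ref <- parse_smiles("c1ccccc1", "ref", canonicalize = FALSE)
  # self-comparison: no atom removal can raise similarity above 1
  sm_self <- similarity_map_weights(ref, ref)
  expect_true(all(sm_self$atom_weights >= -1e-12))
  expect_identical(sm_self$similarity, 1)
  # an atom sharing no bits with the reference cannot lower the similarity
  test <- parse_smiles("Cc1ccccc1", "tol", canonicalize = FALSE)
  sm <- similarity_map_weights(ref, test)
  expect_lte(sm$atom_weights[1], 1e-12)  # the methyl carbon
  # normalization caps |weight| at 1
  expect_lte(max(abs(sm$atom_weights)), 1)
})

test_that("t-SNE: shape, determinism, structure preservation, guards", {
  gm <- gaussian_mixture(mixture_spec(240, 16, 6, 8, seed = 2))
  y1 <- tsne_2d(gm$X, perplexity = 15, seed = 3, max_iter = 250)
  expect_identical(dim(y1), c(240L, 2L))
  y2 <- tsne_2d(gm$X, perplexity = 15, seed = 3, max_iter = 250)
  expect_identical(y1, y2)
  d <- as.matrix(stats::dist(y1))
  same <- outer(gm$labels, gm$labels, "==") & upper.tri(d)
  diff_cl <- (!outer(gm$labels, gm$labels, "==")) & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff_cl]))
  expect_error(tsne_2d(gm$X[1:50, ], perplexity = 30), "perplexity")
})
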