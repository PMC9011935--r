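test_that("parse_smiles counts heavy atoms and bonds", {
  cases <- list(
    list(smiles = "CCO", atoms = 3L, bonds = 2L),
    list(smiles = "O", atoms = 1L, bonds = 0L),
    list(smiles = "C1=CC=CC=C1", atoms = 6L, bonds = 6L),
    list(smiles = "c1ccccc1", atoms = 6L, bonds = 6L),
    list(smiles = "CC(=O)[O-]", atoms = 4L, bonds = 3L),
    list(smiles = "C[C@H](N)C(=O)O", atoms = 6L, bonds = 5L))
  for (cs in cases) {
    m <- parse_smiles(cs$smiles, canonicalize = FALSE)
    expect_identical(m$n_atoms, cs$atoms)
    expect_identical(m$n_bonds, cs$bonds)
  }
})

test_that("parse errors name the offending record and reject empty input", {
  expect_error(parse_smiles("C1CC", id = "rec42", canonicalize = FALSE),
               "rec42", class = "mol_parse_error")
  expect_error(parse_smiles("", id = "empty"), "non-empty")
  expect_error(parse_smiles("notasmiles(", id = "bad", canonicalize = FALSE),
               class = "mol_parse_error")
})

test_that("canonical SMILES round-trips through the parser", {
  for (smi in c("CCO", "c1ccccc1", "CC(=O)[O-]", "O", "C[C@H](N)C(=O)O")) {
    canon <- canonical_smiles(smi)
    m <- parse_smiles(canon)
    expect_identical(m$smiles, canonical_smiles(canon))
  }
})

test_that("atom and bond counts agree with the OpenBabel toolkit", {
  smis <- c("CCO", "c1ccccc1", "CC(C)Cc1ccc(C)cc1C(=O)O",
            "O=[N+]([O-])c1ccc(Cl)cc1")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smis, paste0("m", seq_along(smis)))))
  for (i in seq_along(smis)) {
    m <- parse_smiles(smis[i], canonicalize = FALSE)
    expect_identical(m$n_atoms, nrow(ChemmineR::atomblock(sdf[[i]])))
    expect_identical(m$n_bonds, nrow(ChemmineR::bondblock(sdf[[i]])))
  }
})

test_that("atomic features have the fixed 145-wide Table layout", {
  m <- parse_smiles("c1ccccc1", canonicalize = FALSE)
  f <- featurize_atoms(m)
  expect_identical(ncol(f$values), 145L)
  expect_identical(sum(f$block_layout), 145L)
  expect_identical(unname(f$block_layout),
                   c(118L, 6L, 5L, 4L, 5L, 5L, 1L, 1L))
  # benzene carbon: atom-type one-hot at atomic number 6
  expect_identical(unname(which(f$values[1, 1:118] == 1)), 6L)
  expect_identical(unname(f$values[1, "aromaticity"]), 1)
  expect_equal(unname(f$values[1, "mass"]), 0.12011, tolerance = 1e-12)
})

test_that("hydrogen counts and degenerate molecules featurize correctly", {
  w <- featurize_atoms(parse_smiles("O", canonicalize = FALSE))
  # water oxygen has two implicit hydrogens -> one-hot at category 2
  expect_identical(unname(w$values[1, paste0("n_hydrogens_", 1:5)]),
                   c(0, 0, 1, 0, 0))
  expect_identical(nrow(featurize_bonds(parse_smiles("O",
                                                     canonicalize = FALSE))$values),
                   0L)
  # explicit hydrogens fold into the heavy-atom count
  me <- parse_smiles("C([H])([H])([H])[H]", canonicalize = FALSE)
  expect_identical(me$n_atoms, 1L)
  expect_identical(me$atoms$n_hydrogens, 4L)
})

test_that("bond features have the fixed 12-wide layout with correct blocks", {
  m <- parse_smiles("c1ccccc1", canonicalize = FALSE)
  f <- featurize_bonds(m)
  expect_identical(ncol(f$values), 12L)
  expect_identical(sum(f$block_layout), 12L)
  # aromatic ring bond: type one-hot at "aromatic", conjugated and in ring
  expect_identical(unname(f$values[1, paste0("bond_type_", 1:4)]),
                   c(0, 0, 0, 1))
  expect_identical(unname(f$values[1, "conjugated"]), 1)
  expect_identical(unname(f$values[1, "in_ring"]), 1)
  e <- featurize_bonds(parse_smiles("CCO", canonicalize = FALSE))
  expect_identical(unname(e$values[2, paste0("bond_type_", 1:4)]),
                   c(1, 0, 0, 0))
  expect_identical(unname(e$values[2, "in_ring"]), 0)
  # cis/trans perception lands in the stereo block
  tr <- featurize_bonds(parse_smiles("F/C=C/F", canonicalize = FALSE))
  expect_identical(unname(tr$values[2, paste0("stereo_", 1:6)]),
                   c(0, 0, 0, 0, 0, 1))
  ci <- featurize_bonds(parse_smiles("F/C=C\\F", canonicalize = FALSE))
  expect_identical(unname(ci$values[2, paste0("stereo_", 1:6)]),
                   c(0, 0, 0, 0, 1, 0))
})

test_that("one-hot blocks are exclusive on a varied molecule set", {
  fx <- fixture_smiles(40, seed = 5)
  mols <- parse_molecules(fx, canonicalize = FALSE)
  for (m in mols) {
    fa <- featurize_atoms(m)
    offsets <- cumsum(c(0, fa$block_layout))
    for (b in seq_along(fa$block_layout)) {
      nm <- names(fa$block_layout)[b]
      if (nm %in% c("aromaticity", "mass")) next
      block <- fa$values[, (offsets[b] + 1):offsets[b + 1], drop = FALSE]
      sums <- rowSums(block)
      if (nm == "atom_type") expect_true(all(sums == 1))
      else expect_true(all(sums %in% c(0, 1)))
    }
    expect_true(all(fa$values[, "mass"] > 0))
    expect_true(all(fa$values[, "aromaticity"] %in% c(0, 1)))
    fb <- featurize_bonds(m)
    if (nrow(fb$values) > 0) {
      expect_true(all(rowSums(fb$values[, 1:4, drop = FALSE]) == 1))
    }
  }
})

test_that("featurization is deterministic", {
  m1 <- parse_smiles("CC(C)Cc1ccc(C)cc1C(=O)O", canonicalize = FALSE)
  m2 <- parse_smiles("CC(C)Cc1ccc(C)cc1C(=O)O", canonicalize = FALSE)
  expect_identical(featurize_atoms(m1)$values, featurize_atoms(m2)$values)
  expect_identical(featurize_bonds(m1)$values, featurize_bonds(m2)$values)
})

test_that("global descriptors: reference values and determinism", {
  w <- parse_smiles("O", canonicalize = FALSE)
  d <- suppressWarnings(compute_global_descriptors(w))
  expect_equal(d[["mol_weight"]], 18.015, tolerance = 0.01)
  eth <- parse_smiles("CCO", canonicalize = FALSE)
  d1 <- compute_global_descriptors(eth)
  expect_identical(d1[["n_radical_electrons"]], 0)
  d2 <- compute_global_descriptors(parse_smiles("CCO", canonicalize = FALSE))
  expect_identical(unclass(d1), unclass(d2))
  expect_true(all(is.finite(d1)))
})

test_that("non-finite descriptors are logged and imputed, not propagated", {
  mols <- parse_molecules(data.frame(id = c("w", "e"),
                                     smiles = c("O", "CCO")),
                          canonicalize = FALSE)
  expect_message(dm <- descriptor_table(mols), "imputed")
  expect_true(all(is.finite(dm)))
  imp <- attr(dm, "imputed")
  expect_true(all(imp$molecule == "w"))
})
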