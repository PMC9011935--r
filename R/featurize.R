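#' @name featurize
#' @title One-hot atomic and bond feature matrices
#'
#' @description
#' Every molecule is expanded into two fixed-width one-hot matrices: an atomic
#' feature matrix with one row per heavy atom and a bond feature matrix with
#' one row per bond. The column blocks, in fixed order, are:
#'
#' * atoms (width 145): atom type 118 (one-hot atomic number), degree 6
#'   (0-5), formal charge 5 (-2..+2), chirality 4 (unspecified/CW/CCW/other),
#'   number of bonded hydrogens 5 (0-4), hybridization 5
#'   (sp/sp2/sp3/sp3d/sp3d2), aromaticity 1 (0/1), atomic mass 1 (mass / 100);
#' * bonds (width 12): bond type 4 (single/double/triple/aromatic),
#'   conjugated 1, in-ring 1, stereo 6 (none/any/Z/E/cis/trans).
#'
#' Out-of-range categorical values (degree above 5, charge outside -2..+2,
#' more than 4 hydrogens) are clamped to the last category of their block so
#' the width never varies.
NULL

.ATOM_BLOCKS <- list(
  atom_type = 118L,
  degree = 6L,
  formal_charge = 5L,
  chirality = 4L,
  n_hydrogens = 5L,
  hybridization = 5L,
  aromaticity = 1L,
  mass = 1L)

.BOND_BLOCKS <- list(
  bond_type = 4L,
  conjugated = 1L,
  in_ring = 1L,
  stereo = 6L)

.ATOM_WIDTH <- sum(unlist(.ATOM_BLOCKS))   # 145
.BOND_WIDTH <- sum(unlist(.BOND_BLOCKS))   # 12

.CHIRALITY_LEVELS <- c("unspecified", "CW", "CCW", "other")
.HYBRID_LEVELS <- c("sp", "sp2", "sp3", "sp3d", "sp3d2")
.BOND_TYPE_LEVELS <- c("single", "double", "triple", "aromatic")
.STEREO_LEVELS <- c("none", "any", "Z", "E", "cis", "trans")
.CHARGE_LEVELS <- -2:2

.block_colnames <- function(blocks) {
  unlist(lapply(names(blocks), function(nm) {
    w <- blocks[[nm]]
    if (w == 1L) nm else paste0(nm, "_", seq_len(w))
  }), use.names = FALSE)
}

.one_hot <- function(idx, width, n) {
  # idx: 1-based category per row, clamped into [1, width]
  m <- matrix(0, nrow = n, ncol = width)
  idx <- pmin(pmax(idx, 1L), width)
  m[cbind(seq_len(n), idx)] <- 1
  m
}

#' Atomic feature matrix of a molecule
#'
#' @param mol A `molecule_record` from [parse_smiles()].
#' @return An object of class `atom_features`: list with `values`
#'   (n_atoms x 145 matrix) and `block_layout` (named widths).
#' @export
#' @examples
#' f <- featurize_atoms(parse_smiles("c1ccccc1"))
#' dim(f$values)  # 6 x 145
featurize_atoms <- function(mol) {
  stopifnot(inherits(mol, "molecule_record"))
  a <- mol$atoms
  n <- nrow(a)
  values <- cbind(
    .one_hot(a$atomic_number, 118L, n),
    .one_hot(a$degree + 1L, 6L, n),
    .one_hot(match(pmin(pmax(a$charge, -2L), 2L), .CHARGE_LEVELS), 5L, n),
    .one_hot(match(a$chirality, .CHIRALITY_LEVELS), 4L, n),
    .one_hot(a$n_hydrogens + 1L, 5L, n),
    .one_hot(match(a$hybridization, .HYBRID_LEVELS), 5L, n),
    matrix(as.numeric(a$aromatic), ncol = 1),
    matrix(a$mass / 100, ncol = 1))
  colnames(values) <- .block_colnames(.ATOM_BLOCKS)
  structure(list(values = values, block_layout = unlist(.ATOM_BLOCKS)),
            class = "atom_features")
}

#' Bond feature matrix of a molecule
#'
#' Molecules with no bonds return a 0-row matrix of the fixed width 12; the
#' aggregation step treats that case explicitly.
#'
#' @inheritParams featurize_atoms
#' @return An object of class `bond_features`: list with `values`
#'   (n_bonds x 12 matrix) and `block_layout`.
#' @export
featurize_bonds <- function(mol) {
  stopifnot(inherits(mol, "molecule_record"))
  b <- mol$bonds
  n <- nrow(b)
  if (n == 0L) {
    values <- matrix(0, nrow = 0L, ncol = .BOND_WIDTH)
  } else {
    values <- cbind(
      .one_hot(match(b$order, .BOND_TYPE_LEVELS), 4L, n),
      matrix(as.numeric(b$conjugated), ncol = 1),
      matrix(as.numeric(b$in_ring), ncol = 1),
      .one_hot(match(b$stereo, .STEREO_LEVELS), 6L, n))
  }
  colnames(values) <- .block_colnames(.BOND_BLOCKS)
  structure(list(values = values, block_layout = unlist(.BOND_BLOCKS)),
            class = "bond_features")
}
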