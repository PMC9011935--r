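#' @name feature_engineering
#' @title Fusing local and global features
#'
#' @description
#' Atom and bond feature matrices have molecule-dependent row counts, so they
#' cannot be concatenated across a library directly. The aggregation scheme
#' used here reduces each matrix to a fixed-length vector: the transposed
#' matrix (rows = the fixed 145- or 12-wide feature axis, columns = atoms or
#' bonds) is centered and projected onto its first principal component,
#' giving one score per feature row. Atom and bond scores are concatenated
#' into a 157-long local vector per molecule; a second, dataset-level PCA
#' reduces the molecules x 157 matrix to its top 50 components. Global
#' descriptors are z-scored per column; the two blocks are concatenated and
#' zero-variance columns dropped.
NULL

#' First principal component scores of a matrix
#'
#' Performs PCA on `m` treating columns as variables and rows as
#' observations: each column is centered (no scaling) and the rows are
#' projected on the leading eigenvector of the column covariance matrix.
#' The sign is fixed so that the loading entry with the largest absolute
#' value is positive. Degenerate cases follow documented conventions: a
#' single column returns the centered column; a matrix with zero total
#' variance returns the zero vector.
#'
#' @param m Numeric matrix with `r >= 1` rows and `c >= 1` columns. For the
#'   per-molecule aggregation the caller passes the *transposed* atom (or
#'   bond) matrix so rows are the fixed feature axis.
#' @return Numeric vector of length `nrow(m)`: the PC1 scores.
#' @export
first_pc_scores <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) == 0L || ncol(m) == 0L) {
    return(structure(numeric(0), degenerate = TRUE))
  }
  centered <- sweep(m, 2L, colMeans(m), "-")
  if (ncol(m) == 1L) return(drop(centered))
  if (sum(centered^2) < 1e-24) return(numeric(nrow(m)))
  cv <- crossprod(centered) / (nrow(m) - if (nrow(m) > 1L) 1L else 0L)
  e <- eigen(cv, symmetric = TRUE)
  v1 <- e$vectors[, 1L]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  drop(centered %*% v1)
}

#' Aggregate the local features of one molecule into a fixed-length vector
#'
#' Concatenates the PC1 scores of the transposed atomic matrix (length 145)
#' and of the transposed bond matrix (length 12). Bond-free molecules
#' contribute a zero vector for the bond part.
#'
#' @param atoms An `atom_features` object.
#' @param bonds A `bond_features` object.
#' @return Numeric vector of length 157 (classes `local_features`).
#' @export
aggregate_local <- function(atoms, bonds) {
  stopifnot(inherits(atoms, "atom_features"), inherits(bonds, "bond_features"))
  stopifnot(nrow(atoms$values) >= 1L)
  a_part <- first_pc_scores(t(atoms$values))
  b_part <- if (nrow(bonds$values) == 0L) numeric(.BOND_WIDTH)
            else first_pc_scores(t(bonds$values))
  out <- c(a_part, b_part)
  names(out) <- c(paste0("atom_", colnames(atoms$values)),
                  paste0("bond_", colnames(bonds$values)))
  structure(out, class = "local_features")
}

#' Local feature matrix for a list of molecules
#'
#' @param mols List of `molecule_record`s.
#' @return Numeric matrix (molecules x 157), molecule ids as row names.
#' @export
local_feature_matrix <- function(mols) {
  rows <- lapply(mols, function(m) {
    unclass(aggregate_local(featurize_atoms(m), featurize_bonds(m)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(mols, `[[`, "", "id")
  out
}

#' Dataset-level PCA of the aggregated local features
#'
#' Centers the molecules x 157 matrix column-wise (no scaling) and returns
#' the scores on the leading `n_components` principal components, ordered by
#' decreasing variance.
#'
#' @param local Numeric matrix, molecules x local features.
#' @param n_components Number of components to keep (default 50).
#' @return Matrix of scores (molecules x `n_components`) with columns
#'   `"PCA 1"`, ..., and attribute `"explained_variance_ratio"`.
#' @export
reduce_local_dataset <- function(local, n_components = 50L) {
  stopifnot(is.matrix(local))
  if (nrow(local) < n_components) {
    stop("n_components (", n_components, ") exceeds the number of molecules (",
         nrow(local), "); choose a smaller n_components", call. = FALSE)
  }
  pc <- stats::prcomp(local, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (k < n_components) {
    # rank-deficient input: pad with zero-variance score columns
    scores <- cbind(scores, matrix(0, nrow(local), n_components - k))
  }
  colnames(scores) <- paste("PCA", seq_len(n_components))
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  attr(scores, "explained_variance_ratio") <- evr[seq_len(min(n_components,
                                                              length(evr)))]
  scores
}

#' Z-score the columns of a descriptor matrix
#'
#' Each column is transformed to mean 0 and population standard deviation 1
#' (divide by `n`, not `n - 1`). Columns with (near-)zero variance become
#' all-zero and are flagged in the `"constant"` attribute for the
#' zero-variance filter.
#'
#' @param global Numeric matrix, molecules x descriptors, `m >= 2` rows.
#' @param tol Standard deviations below `tol` count as constant.
#' @return Matrix of the same shape; attribute `"constant"` is a logical
#'   vector per column.
#' @export
zscore_columns <- function(global, tol = 1e-12) {
  stopifnot(is.matrix(global), nrow(global) >= 2L)
  mu <- colMeans(global)
  sd_pop <- sqrt(pmax(colMeans(global^2) - mu^2, 0))
  constant <- sd_pop < tol
  out <- sweep(global, 2L, mu, "-")
  out <- sweep(out, 2L, ifelse(constant, 1, sd_pop), "/")
  out[, constant] <- 0
  attr(out, "constant") <- constant
  out
}

#' Assemble the fused feature table
#'
#' Concatenates the 50 aggregated local components and the z-scored global
#' descriptors, then removes zero-variance columns (population SD below
#' `tol`). Dropped column names are recorded.
#'
#' @param local_reduced Matrix from [reduce_local_dataset()].
#' @param global_z Matrix from [zscore_columns()].
#' @param tol Zero-variance threshold on the column SD.
#' @return An object of class `feature_table`: list with `values` (m x p
#'   matrix), `column_labels`, `provenance` (`"local"`/`"global"` per
#'   column) and `dropped` (names of removed columns).
#' @export
assemble_feature_table <- function(local_reduced, global_z, tol = 1e-12) {
  stopifnot(is.matrix(local_reduced), is.matrix(global_z))
  if (nrow(local_reduced) != nrow(global_z)) {
    stop("local and global blocks disagree on the number of molecules (",
         nrow(local_reduced), " vs ", nrow(global_z), ")", call. = FALSE)
  }
  values <- cbind(local_reduced, global_z)
  provenance <- c(rep("local", ncol(local_reduced)),
                  rep("global", ncol(global_z)))
  mu <- colMeans(values)
  sd_pop <- sqrt(pmax(colMeans(values^2) - mu^2, 0))
  keep <- sd_pop >= tol
  dropped <- colnames(values)[!keep]
  structure(list(
    values = values[, keep, drop = FALSE],
    column_labels = colnames(values)[keep],
    provenance = provenance[keep],
    dropped = dropped), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table>  %d molecules x %d features (%d local, %d global)\n",
              nrow(x$values), ncol(x$values),
              sum(x$provenance == "local"), sum(x$provenance == "global")))
  if (length(x$dropped) > 0L) {
    cat("  dropped zero-variance columns:",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the full feature-engineering pipeline on parsed molecules
#'
#' Convenience wrapper: local featurization and aggregation, dataset PCA to
#' `n_components`, descriptor computation and z-scoring, fusion and
#' zero-variance filtering.
#'
#' @param mols List of `molecule_record`s.
#' @param n_components Local components to keep (default 50; reduced with a
#'   warning when fewer molecules are available).
#' @param descriptor_set Passed to [descriptor_table()].
#' @return A `feature_table`; attribute `"metadata"` carries the descriptor
#'   set, explained-variance ratios and imputation log.
#' @export
engineer_features <- function(mols, n_components = 50L, descriptor_set = NULL) {
  local <- local_feature_matrix(mols)
  if (nrow(local) < n_components) {
    warning("only ", nrow(local), " molecules; reducing n_components from ",
            n_components, call. = FALSE)
    n_components <- nrow(local)
  }
  reduced <- reduce_local_dataset(local, n_components)
  global <- descriptor_table(mols, descriptor_set)
  gz <- zscore_columns(global)
  ft <- assemble_feature_table(reduced, gz)
  attr(ft, "metadata") <- list(
    n_molecules = length(mols),
    descriptor_set = attr(global, "descriptor_set"),
    d_g = ncol(global),
    explained_variance_ratio =
      as.numeric(attr(reduced, "explained_variance_ratio")),
    imputed = attr(global, "imputed"),
    constant_descriptors = colnames(global)[attr(gz, "constant")],
    dropped_columns = ft$dropped)
  ft
}
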