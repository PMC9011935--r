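#' @name similarity
#' @title Circular fingerprints, Tanimoto similarity and similarity maps
#'
#' @description
#' Extended-connectivity fingerprints hash circular atom neighborhoods of
#' increasing radius into a fixed-length bit (binary) or count vector. Each
#' atom starts from an invariant built from its element, degree, hydrogen
#' count, charge, ring membership and aromaticity; at every iteration the
#' invariant is re-hashed together with the sorted (bond type, neighbour
#' invariant) pairs, and every (atom, radius) environment contributes one
#' folded bit. The atoms spanned by each environment are retained so that
#' similarity maps can remove an atom's bits and measure the similarity
#' drop.
#'
#' All environments are kept (no duplicate-environment pruning), so counts
#' reflect every circular neighbourhood; like all folded fingerprints the
#' exact bit values are implementation-specific, and similarities should be
#' compared within one toolkit only.
#'
#' Default parameters follow common practice for the two use cases:
#' similarity maps use counted fingerprints with radius 2 and 2048 bits,
#' similarity matrices binary fingerprints with radius 1 and 2048 bits.
NULL

# deterministic polynomial hash of an integer vector into [0, 2^31 - 2]
.hash_ints <- function(v) {
  h <- 17
  for (x in v) {
    h <- (h * 92821 + (x %% 2147483647)) %% 2147483647
  }
  h
}

.BOND_CODE <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)

#' Extended-connectivity fingerprint of a molecule
#'
#' @param mol A `molecule_record`.
#' @param radius Neighbourhood radius (default 2).
#' @param n_bits Folded length (default 2048).
#' @param counted `TRUE` for a count fingerprint, `FALSE` for binary.
#' @return An object of class `ecfp`: list with `kind`, `radius`, `n_bits`,
#'   `bits` (sorted unique bit ids in `0 .. n_bits-1`), `counts` (parallel
#'   integer vector; all 1 for binary), and `features` — a list with one
#'   entry per (atom, radius) environment: `bit`, `center`, `radius`,
#'   `atoms` (indices covered by the environment).
#' @export
ecfp <- function(mol, radius = 2L, n_bits = 2048L, counted = TRUE) {
  stopifnot(inherits(mol, "molecule_record"), radius >= 0L, n_bits >= 1L)
  a <- mol$atoms
  b <- mol$bonds
  n <- nrow(a)
  atom_in_ring <- rep(FALSE, n)
  if (nrow(b) > 0L) {
    atom_in_ring[unique(c(b$begin[b$in_ring], b$end[b$in_ring]))] <- TRUE
  }
  inv <- vapply(seq_len(n), function(i) {
    .hash_ints(c(a$atomic_number[i], a$degree[i], a$n_hydrogens[i],
                 a$charge[i] + 10L, as.integer(atom_in_ring[i]),
                 as.integer(a$aromatic[i])))
  }, numeric(1))
  env <- as.list(seq_len(n))
  nbrs <- lapply(seq_len(n), function(i) {
    sel <- b$begin == i | b$end == i
    if (!any(sel)) return(NULL)
    data.frame(atom = ifelse(b$begin[sel] == i, b$end[sel], b$begin[sel]),
               code = .BOND_CODE[b$order[sel]])
  })

  features <- vector("list", n * (radius + 1L))
  fi <- 0L
  for (i in seq_len(n)) {
    fi <- fi + 1L
    features[[fi]] <- list(bit = inv[i] %% n_bits, center = i, radius = 0L,
                           atoms = i)
  }
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      new_inv <- inv
      new_env <- env
      for (i in seq_len(n)) {
        nb <- nbrs[[i]]
        if (is.null(nb)) {
          new_inv[i] <- .hash_ints(c(r, inv[i]))
        } else {
          pairs <- cbind(nb$code, inv[nb$atom])
          ord <- order(pairs[, 1L], pairs[, 2L])
          new_inv[i] <- .hash_ints(c(r, inv[i], t(pairs[ord, , drop = FALSE])))
          new_env[[i]] <- sort(unique(c(env[[i]],
                                        unlist(env[nb$atom]))))
        }
        fi <- fi + 1L
        features[[fi]] <- list(bit = new_inv[i] %% n_bits, center = i,
                               radius = r, atoms = new_env[[i]])
      }
      inv <- new_inv
      env <- new_env
    }
  }
  features <- features[seq_len(fi)]
  .ecfp_from_features(features, mol$id, radius, n_bits, counted)
}

.ecfp_from_features <- function(features, id, radius, n_bits, counted) {
  bit_of <- vapply(features, `[[`, numeric(1), "bit")
  tab <- table(bit_of)
  bits <- as.numeric(names(tab))
  counts <- as.integer(tab)
  if (!counted) counts <- rep(1L, length(bits))
  structure(list(
    id = id,
    kind = if (counted) "count" else "binary",
    radius = as.integer(radius),
    n_bits = as.integer(n_bits),
    bits = bits,
    counts = counts,
    features = features), class = "ecfp")
}

#' @export
print.ecfp <- function(x, ...) {
  cat(sprintf("<ecfp '%s'>  %s, radius %d, %d/%d bits set\n",
              x$id, x$kind, x$radius, length(x$bits), x$n_bits))
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' Binary fingerprints use `|A intersect B| / |A union B|`; count
#' fingerprints the generalization `sum_i min(a_i, b_i) / sum_i max(a_i,
#' b_i)`. Two empty fingerprints compare as 0 with a warning.
#'
#' @param a,b `ecfp` objects with identical kind, radius and length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "ecfp"), inherits(b, "ecfp"))
  if (a$kind != b$kind || a$radius != b$radius || a$n_bits != b$n_bits) {
    stop("fingerprints have mismatched parameters (kind/radius/n_bits)",
         call. = FALSE)
  }
  if (length(a$bits) == 0L && length(b$bits) == 0L) {
    warning("both fingerprints are empty; similarity defined as 0",
            call. = FALSE)
    return(0)
  }
  all_bits <- union(a$bits, b$bits)
  ca <- cb <- numeric(length(all_bits))
  ca[match(a$bits, all_bits)] <- a$counts
  cb[match(b$bits, all_bits)] <- b$counts
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param mols List of `molecule_record`s.
#' @param radius,n_bits,counted Fingerprint parameters; defaults match the
#'   similarity-matrix convention (binary, radius 1, 2048 bits).
#' @return Symmetric matrix with unit diagonal, molecule ids as dimnames.
#' @export
tanimoto_matrix <- function(mols, radius = 1L, n_bits = 2048L,
                            counted = FALSE) {
  fps <- lapply(mols, ecfp, radius = radius, n_bits = n_bits,
                counted = counted)
  n <- length(fps)
  out <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        out[i, j] <- out[j, i] <- tanimoto(fps[[i]], fps[[j]])
      }
    }
  }
  ids <- vapply(mols, `[[`, "", "id")
  dimnames(out) <- list(ids, ids)
  out
}

#' Atom-weighted similarity map between two molecules
#'
#' For every atom of the test molecule, the weight is the drop in Tanimoto
#' similarity to the reference when the fingerprint bits whose circular
#' environments contain that atom are removed:
#' `w_a = sim(ref, test) - sim(ref, test \ bits(a))`. Positive weights mark
#' substructures that increase the similarity, negative weights the
#' opposite. Weights are normalized to a maximum absolute value of 1 for
#' rendering (unless all are zero).
#'
#' @param ref,test `molecule_record`s.
#' @param radius,n_bits Fingerprint parameters (counted fingerprints;
#'   defaults radius 2, 2048 bits per the similarity-map convention).
#' @param normalize Normalize weights by `max(abs(w))` (default `TRUE`).
#' @return An object of class `similarity_map`: list with `reference_id`,
#'   `test_id`, `similarity`, `atom_weights` (length = test heavy atoms) and
#'   `raw_weights`.
#' @export
similarity_map_weights <- function(ref, test, radius = 2L, n_bits = 2048L,
                                   normalize = TRUE) {
  fp_ref <- ecfp(ref, radius = radius, n_bits = n_bits, counted = TRUE)
  fp_test <- ecfp(test, radius = radius, n_bits = n_bits, counted = TRUE)
  base_sim <- tanimoto(fp_ref, fp_test)
  n <- test$n_atoms
  raw <- numeric(n)
  for (atom in seq_len(n)) {
    keep <- !vapply(fp_test$features, function(f) atom %in% f$atoms,
                    logical(1))
    fp_removed <- .ecfp_from_features(fp_test$features[keep], test$id,
                                      radius, n_bits, counted = TRUE)
    sim_removed <- if (length(fp_removed$bits) == 0L) 0
                   else tanimoto(fp_ref, fp_removed)
    raw[atom] <- base_sim - sim_removed
  }
  weights <- raw
  if (normalize && max(abs(raw)) > 0) weights <- raw / max(abs(raw))
  structure(list(reference_id = ref$id, test_id = test$id,
                 similarity = base_sim, atom_weights = weights,
                 raw_weights = raw), class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf("<similarity_map>  ref '%s' vs test '%s': Tanimoto %.3f\n",
              x$reference_id, x$test_id, x$similarity))
  cat("  atom weights:", paste(sprintf("%.2f", x$atom_weights),
                               collapse = " "), "\n")
  invisible(x)
}
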