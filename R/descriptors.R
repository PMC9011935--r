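#' @name descriptors
#' @title Global molecular descriptors
#'
#' @description
#' Whole-molecule descriptors form the "global" feature set that is z-scored
#' and fused with the PCA-aggregated local features. The default collection
#' combines two sources:
#'
#' * a suite of constitutional and topological descriptors computed
#'   in-package from the molecular graph (molecular weight, atom/bond/ring
#'   counts, element counts, hydrogen-bond donor/acceptor counts, rotatable
#'   bonds, fraction of sp3 carbons, Wiener index, Balaban's J, Zagreb
#'   indices, Randic connectivity, kappa shape indices, eccentric
#'   connectivity, graph diameter/radius, ...);
#' * physicochemical properties from OpenBabel (via \pkg{ChemmineOB}):
#'   logP, TPSA, molar refractivity and Lipinski donor/acceptor counts.
#'
#' The descriptor count `D_g` depends on the toolkit in use and is recorded
#' in run metadata. A descriptor evaluating to `NA`/`NaN`/`Inf` for a
#' molecule is logged and imputed to 0 before z-scoring; it is never
#' propagated silently.
NULL

.OB_DESCRIPTORS <- c("logP", "TPSA", "MR", "HBA1", "HBD")

#' Names of the default global descriptor set
#'
#' @param include_openbabel Include the OpenBabel physicochemical properties.
#' @return Character vector of descriptor names (the default `D_g`).
#' @export
mol_descriptor_names <- function(include_openbabel = TRUE) {
  graph_names <- names(.graph_descriptors(parse_smiles("CCO", canonicalize = FALSE)))
  if (include_openbabel) c(graph_names, .OB_DESCRIPTORS) else graph_names
}

#' Compute global descriptors for one molecule
#'
#' @param mol A `molecule_record`.
#' @param descriptor_set Character vector of descriptor names; defaults to
#'   the full collection of [mol_descriptor_names()]. Must be identical for
#'   every molecule in a run.
#' @param ob_row Optional named numeric vector of precomputed OpenBabel
#'   properties for this molecule (used by the batch path to avoid one
#'   OpenBabel call per molecule).
#' @return A named numeric vector of class `global_descriptors`, finite
#'   everywhere; non-finite raw values are imputed to 0 with a warning.
#' @export
#' @examples
#' d <- compute_global_descriptors(parse_smiles("O"))
#' d[["mol_weight"]]  # 18.015
compute_global_descriptors <- function(mol, descriptor_set = NULL,
                                       ob_row = NULL) {
  stopifnot(inherits(mol, "molecule_record"))
  vals <- .graph_descriptors(mol)
  if (is.null(descriptor_set)) {
    descriptor_set <- c(names(vals), .OB_DESCRIPTORS)
  }
  need_ob <- intersect(descriptor_set, .OB_DESCRIPTORS)
  if (length(need_ob) > 0L) {
    if (is.null(ob_row)) ob_row <- .ob_descriptors(mol$smiles)[1, ]
    vals <- c(vals, ob_row)
  }
  missing <- setdiff(descriptor_set, names(vals))
  if (length(missing) > 0L) {
    stop("unknown descriptor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- vals[descriptor_set]
  bad <- !is.finite(out)
  if (any(bad)) {
    warning(sprintf("molecule '%s': non-finite descriptor(s) %s imputed to 0",
                    mol$id, paste(descriptor_set[bad], collapse = ", ")),
            call. = FALSE)
    out[bad] <- 0
  }
  structure(out, class = "global_descriptors")
}

#' Global descriptor matrix for a set of molecules
#'
#' Batch version of [compute_global_descriptors()]: OpenBabel properties are
#' computed in a single call, graph descriptors per molecule. Non-finite
#' entries are imputed to 0; the affected (molecule, descriptor) pairs are
#' recorded in the `"imputed"` attribute.
#'
#' @param mols List of `molecule_record`s.
#' @param descriptor_set As in [compute_global_descriptors()].
#' @return Numeric matrix (molecules x descriptors) with molecule ids as row
#'   names; attributes `"imputed"` (data frame) and `"descriptor_set"`.
#' @export
descriptor_table <- function(mols, descriptor_set = NULL) {
  stopifnot(length(mols) >= 1L)
  if (is.null(descriptor_set)) descriptor_set <- mol_descriptor_names()
  need_ob <- length(intersect(descriptor_set, .OB_DESCRIPTORS)) > 0L
  ob <- NULL
  if (need_ob) {
    ob <- .ob_descriptors(vapply(mols, `[[`, "", "smiles"))
  }
  rows <- lapply(seq_along(mols), function(i) {
    vals <- .graph_descriptors(mols[[i]])
    if (need_ob) vals <- c(vals, ob[i, ])
    vals[descriptor_set]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(mols, `[[`, "", "id")
  colnames(m) <- descriptor_set
  raw <- m
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    message(sprintf("descriptor_table: %d non-finite value(s) imputed to 0",
                    nrow(bad)))
    m[bad] <- 0
  }
  attr(m, "imputed") <- if (nrow(bad) > 0L)
    data.frame(molecule = rownames(raw)[bad[, 1]],
               descriptor = colnames(raw)[bad[, 2]])
    else data.frame(molecule = character(0), descriptor = character(0))
  attr(m, "descriptor_set") <- descriptor_set
  m
}

# OpenBabel physicochemical properties for a SMILES vector, one batched
# conversion. Molecules OpenBabel cannot represent as a valid molfile (for
# example single-atom species) get NA rows, imputed downstream per policy.
.ob_descriptors <- function(smiles) {
  out <- matrix(NA_real_, nrow = length(smiles),
                ncol = length(.OB_DESCRIPTORS),
                dimnames = list(NULL, .OB_DESCRIPTORS))
  names(smiles) <- sprintf("m%06d", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  if (is.null(sdf)) return(out)
  ok <- tryCatch(ChemmineR::validSDF(sdf), error = function(e) NULL)
  if (is.null(ok) || !any(ok)) return(out)
  props <- tryCatch(ChemmineR::propOB(sdf[which(ok)]),
                    error = function(e) NULL)
  if (is.null(props)) return(out)
  idx <- match(rownames(props), names(smiles))
  for (nm in .OB_DESCRIPTORS) out[idx, nm] <- as.numeric(props[[nm]])
  out
}

# --- in-package graph descriptor suite --------------------------------------

.graph_descriptors <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  na <- nrow(a)
  nb <- nrow(b)
  el <- a$element
  deg <- a$degree
  nH <- a$n_hydrogens

  g <- igraph::make_empty_graph(n = na, directed = FALSE)
  if (nb > 0L) g <- igraph::add_edges(g, rbind(b$begin, b$end))
  comp <- igraph::components(g)$no
  D <- igraph::distances(g)
  finite_pairs <- is.finite(D) & upper.tri(D)
  wiener <- sum(D[finite_pairs])
  ecc <- apply(D, 1, function(r) max(r[is.finite(r)]))
  diam <- if (na > 1L) max(ecc) else 0
  radius <- if (na > 1L) min(ecc) else 0

  mu <- nb - na + comp  # cyclomatic number (ring count)
  halogens <- c("F", "Cl", "Br", "I", "At")

  # Balaban J: m/(mu+1) * sum over edges of 1/sqrt(s_i s_j), s = distance sums
  balaban <- 0
  if (nb > 0L) {
    s <- rowSums(ifelse(is.finite(D), D, 0))
    ss <- s[b$begin] * s[b$end]
    balaban <- if (all(ss > 0)) nb / (mu + 1) * sum(1 / sqrt(ss)) else NaN
  }

  # Kier kappa shape indices from path counts
  p1 <- nb
  p2 <- sum(choose(deg, 2))
  tri <- if (na >= 3L) sum(igraph::count_triangles(g)) / 3 else 0
  p3 <- if (nb > 0L) sum((deg[b$begin] - 1) * (deg[b$end] - 1)) - 3 * tri else 0
  kappa1 <- if (p1 > 0) na * (na - 1)^2 / p1^2 else 0
  kappa2 <- if (p2 > 0) (na - 1) * (na - 2)^2 / p2^2 else 0
  kappa3 <- if (p3 > 0) {
    if (na %% 2L == 1L) (na - 1) * (na - 3)^2 / p3^2
    else (na - 3) * (na - 2)^2 / p3^2
  } else 0

  rot <- 0L
  if (nb > 0L) {
    rot <- sum(b$order == "single" & !b$in_ring &
                 deg[b$begin] > 1L & deg[b$end] > 1L)
  }
  is_c <- el == "C"
  sp3_c <- is_c & a$hybridization == "sp3"

  c(
    mol_weight = sum(a$mass) + sum(nH) * .ELEMENT_MASSES[["H"]],
    heavy_atom_count = na,
    bond_count = nb,
    ring_count = mu,
    n_components = comp,
    n_aromatic_atoms = sum(a$aromatic),
    n_aromatic_bonds = if (nb > 0L) sum(b$aromatic) else 0,
    n_heteroatoms = sum(!is_c & el != "H"),
    n_halogens = sum(el %in% halogens),
    n_nitrogen = sum(el == "N"),
    n_oxygen = sum(el == "O"),
    n_sulfur = sum(el == "S"),
    n_phosphorus = sum(el == "P"),
    n_fluorine = sum(el == "F"),
    n_chlorine = sum(el == "Cl"),
    n_hydrogens_total = sum(nH),
    n_hbd = sum(el %in% c("N", "O") & nH > 0L),
    n_hba = sum(el %in% c("N", "O")),
    n_rotatable_bonds = rot,
    n_double_bonds = if (nb > 0L) sum(b$order == "double") else 0,
    n_triple_bonds = if (nb > 0L) sum(b$order == "triple") else 0,
    n_ring_bonds = if (nb > 0L) sum(b$in_ring) else 0,
    frac_csp3 = if (sum(is_c) > 0L) sum(sp3_c) / sum(is_c) else 0,
    total_formal_charge = sum(a$charge),
    abs_formal_charge = sum(abs(a$charge)),
    n_radical_electrons = 0,  # closed-shell valence model
    mean_atomic_mass = mean(a$mass),
    wiener_index = wiener,
    balaban_j = balaban,
    zagreb_m1 = sum(deg^2),
    zagreb_m2 = if (nb > 0L) sum(deg[b$begin] * deg[b$end]) else 0,
    randic_chi0 = sum(ifelse(deg > 0, 1 / sqrt(deg), 0)),
    randic_chi1 = if (nb > 0L) sum(1 / sqrt(deg[b$begin] * deg[b$end])) else 0,
    kappa1 = kappa1,
    kappa2 = kappa2,
    kappa3 = kappa3,
    eccentric_connectivity = sum(deg * ecc),
    graph_diameter = diam,
    graph_radius = radius,
    mean_degree = mean(deg))
}
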