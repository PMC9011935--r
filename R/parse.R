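#' Parse a SMILES string into a molecule record
#'
#' Builds the molecular graph (heavy atoms and the bonds between them) from a
#' SMILES string, together with the per-atom and per-bond attributes the
#' featurizer consumes: element, formal charge, aromaticity, tetrahedral
#' chirality, implicit/explicit hydrogen counts, hybridization, bond order,
#' conjugation, ring membership and double-bond cis/trans stereo. Hydrogens
#' stay implicit: explicit `[H]` atoms in the input are folded into the
#' hydrogen count of their heavy neighbour and are not nodes of the graph.
#'
#' The grammar covers the SMILES organic subset (B, C, N, O, P, S, F, Cl, Br,
#' I and their aromatic lowercase forms), bracket atoms with isotope, `@`/`@@`
#' chirality, hydrogen count and charge, branches, ring-closure digits
#' (including `%nn`), dot-separated fragments, and the bond symbols
#' `- = # : / \`. Implicit hydrogen counts for unbracketed atoms follow the
#' standard smallest-sufficient-valence rule.
#'
#' @param smiles A single non-empty SMILES string.
#' @param id Identifier used in error messages and downstream tables.
#' @param canonicalize If `TRUE` (default) the canonical form is computed with
#'   OpenBabel (via \pkg{ChemmineOB}) and stored in `$smiles`; on failure the
#'   input string is kept with a warning.
#'
#' @return An object of class `molecule_record`: a list with elements `id`,
#'   `smiles` (canonical), `input_smiles`, `n_atoms`, `n_bonds`, `atoms`
#'   (data frame: element, atomic_number, aromatic, charge, chirality,
#'   n_hydrogens, degree, hybridization, mass) and `bonds` (data frame:
#'   begin, end, order, aromatic, conjugated, in_ring, stereo).
#' @export
#' @examples
#' m <- parse_smiles("CCO", id = "ethanol")
#' m$n_atoms  # 3 heavy atoms
#' m$n_bonds  # 2 bonds
parse_smiles <- function(smiles, id = "mol", canonicalize = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop_parse(id, "SMILES must be a single non-empty string")
  }
  g <- tryCatch(
    .smiles_to_graph(smiles),
    error = function(e) {
      if (inherits(e, "mol_parse_error")) stop(e)
      stop_parse(id, conditionMessage(e))
    })
  g <- .fold_explicit_hydrogens(g, id)
  if (nrow(g$atoms) == 0L) stop_parse(id, "no heavy atoms in SMILES")
  g <- .perceive(g, id)

  canonical <- smiles
  if (isTRUE(canonicalize)) {
    canonical <- tryCatch(canonical_smiles(smiles), error = function(e) {
      warning("canonicalization failed for '", id, "'; keeping input string",
              call. = FALSE)
      smiles
    })
  }

  structure(list(
    id = as.character(id),
    smiles = canonical,
    input_smiles = smiles,
    n_atoms = nrow(g$atoms),
    n_bonds = nrow(g$bonds),
    atoms = g$atoms,
    bonds = g$bonds), class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record '%s'>  %s\n", x$id, x$smiles))
  cat(sprintf("  %d heavy atoms, %d bonds\n", x$n_atoms, x$n_bonds))
  invisible(x)
}

#' Canonicalize a SMILES string with OpenBabel
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length.
#' @export
canonical_smiles <- function(smiles) {
  out <- ChemmineOB::convertFormat(
    "SMI", "CAN", paste0(paste(smiles, collapse = "\n"), "\n"))
  out <- strsplit(out, "\n", fixed = TRUE)[[1]]
  out <- sub("\t.*$", "", out)
  out <- trimws(out)
  out <- out[nzchar(out)]
  if (length(out) != length(smiles)) {
    stop("OpenBabel failed to canonicalize ",
         length(smiles) - length(out), " of ", length(smiles), " SMILES",
         call. = FALSE)
  }
  out
}

stop_parse <- function(id, msg) {
  stop(structure(class = c("mol_parse_error", "error", "condition"),
                 list(message = sprintf("record '%s': %s", id, msg),
                      call = NULL)))
}

# --- tokenizer / graph builder ----------------------------------------------

.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.smiles_to_graph <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()    # each: element, aromatic, charge, hcount (NA = implicit),
                     # chirality, bracket
  bonds <- list()    # each: begin, end, sym ("" = default)
  stack <- integer(0)
  prev <- NA_integer_
  pending <- ""      # pending bond symbol
  ring <- list()     # open ring closures: key -> list(atom, sym)

  add_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_,
                       chirality = "unspecified", bracket = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = charge,
      hcount = hcount, chirality = chirality, bracket = bracket)
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(begin = prev, end = idx,
                                           sym = pending)
    }
    pending <<- ""
    prev <<- idx
    idx
  }

  close_ring <- function(key) {
    if (is.na(prev)) stop("ring-closure digit before any atom")
    if (!is.null(ring[[key]])) {
      op <- ring[[key]]
      sym <- pending
      if (sym == "" && op$sym != "") sym <- op$sym
      if (op$sym != "" && pending != "" && op$sym != pending &&
          !(op$sym %in% c("/", "\\") && pending %in% c("/", "\\"))) {
        stop("conflicting bond symbols at ring closure ", key)
      }
      if (op$atom == prev) stop("ring closure bonds an atom to itself")
      bonds[[length(bonds) + 1L]] <<- list(begin = op$atom, end = prev,
                                           sym = sym)
      ring[[key]] <<- NULL
      pending <<- ""
    } else {
      ring[[key]] <<- list(atom = prev, sym = pending)
      pending <<- ""
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) stop("branch opened before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- ""
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}", paste0(chars[i + 1L], chars[i + 2L])))
        stop("'%' must be followed by two digits")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated '['")
      tok <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      a <- .parse_bracket_atom(tok)
      add_atom(a$element, a$aromatic, a$charge, a$hcount, a$chirality,
               bracket = TRUE)
      i <- j + 1L
    } else {
      # organic-subset atom, two-letter symbols first
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE)
        i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        add_atom(ch, FALSE)
        i <- i + 1L
      } else if (ch %in% .AROMATIC_ORGANIC) {
        add_atom(toupper(ch), TRUE)
        i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' at position ", i)
      }
    }
  }
  if (length(stack) > 0L) stop("unmatched '('")
  if (length(ring) > 0L)
    stop("unclosed ring bond(s): ", paste(names(ring), collapse = ", "))
  if (length(atoms) == 0L) stop("no atoms found")

  list(
    atoms = data.frame(
      element = vapply(atoms, `[[`, "", "element"),
      aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
      charge = vapply(atoms, `[[`, 0L, "charge"),
      hcount = vapply(atoms, `[[`, NA_integer_, "hcount"),
      chirality = vapply(atoms, `[[`, "", "chirality"),
      bracket = vapply(atoms, `[[`, FALSE, "bracket"),
      stringsAsFactors = FALSE),
    bonds = if (length(bonds)) data.frame(
      begin = vapply(bonds, `[[`, 0L, "begin"),
      end = vapply(bonds, `[[`, 0L, "end"),
      sym = vapply(bonds, `[[`, "", "sym"),
      stringsAsFactors = FALSE)
    else data.frame(begin = integer(0), end = integer(0),
                    sym = character(0), stringsAsFactors = FALSE))
}

# Bracket atom body, e.g. "13CH4", "O-", "N+", "C@@H", "nH", "Fe+2".
.parse_bracket_atom <- function(tok) {
  m <- regmatches(tok, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{1,2}|@[A-Z]{2}[0-9]+)?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?([:][0-9]+)?$",
    tok))[[1]]
  if (length(m) == 0L) stop("cannot parse bracket atom '[", tok, "]'")
  sym <- m[3]
  aromatic <- sym %in% .AROMATIC_ORGANIC ||
    (nchar(sym) == 1L && sym == tolower(sym) && sym %in% .AROMATIC_ORGANIC)
  if (aromatic || sym %in% c("se", "as", "te")) {
    element <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
    aromatic <- TRUE
  } else {
    element <- sym
  }
  if (!element %in% .ELEMENT_SYMBOLS)
    stop("unknown element '", element, "' in bracket atom '[", tok, "]'")
  chir <- m[4]
  chirality <- if (chir == "") "unspecified"
    else if (chir == "@@") "CW"
    else if (chir == "@") "CCW"
    else "other"
  hfield <- m[5]
  hcount <- if (hfield == "") 0L
    else if (hfield == "H") 1L
    else as.integer(substr(hfield, 2, nchar(hfield)))
  cfield <- m[6]
  charge <- if (cfield == "") 0L
    else if (grepl("^[+]+$", cfield)) nchar(cfield)
    else if (grepl("^[-]+$", cfield)) -nchar(cfield)
    else as.integer(paste0(substr(cfield, 1, 1),
                           ifelse(nchar(cfield) == 1L, "1",
                                  substr(cfield, 2, nchar(cfield)))))
  list(element = element, aromatic = aromatic, charge = as.integer(charge),
       hcount = hcount, chirality = chirality)
}

# Merge explicit [H] nodes into the hydrogen count of their heavy neighbour.
.fold_explicit_hydrogens <- function(g, id) {
  is_h <- g$atoms$element == "H"
  if (!any(is_h)) return(g)
  h_idx <- which(is_h)
  extra <- integer(nrow(g$atoms))
  drop_bond <- logical(nrow(g$bonds))
  for (h in h_idx) {
    nb <- c(g$bonds$end[g$bonds$begin == h], g$bonds$begin[g$bonds$end == h])
    if (length(nb) != 1L)
      stop_parse(id, "explicit hydrogen must have exactly one bond")
    if (nb %in% h_idx) stop_parse(id, "H-H bond not supported")
    extra[nb] <- extra[nb] + 1L + max(0L, g$atoms$hcount[h], na.rm = TRUE)
    drop_bond[g$bonds$begin == h | g$bonds$end == h] <- TRUE
  }
  keep <- !is_h
  remap <- cumsum(keep)
  atoms <- g$atoms[keep, , drop = FALSE]
  atoms$hcount <- ifelse(is.na(atoms$hcount), NA_integer_,
                         atoms$hcount + extra[keep])
  atoms$.explicit_h <- extra[keep]
  bonds <- g$bonds[!drop_bond, , drop = FALSE]
  bonds$begin <- remap[bonds$begin]
  bonds$end <- remap[bonds$end]
  rownames(atoms) <- rownames(bonds) <- NULL
  list(atoms = atoms, bonds = bonds)
}

# --- perception: orders, rings, implicit H, hybridization, conjugation, stereo
.perceive <- function(g, id) {
  atoms <- g$atoms
  bonds <- g$bonds
  na <- nrow(atoms)
  nb <- nrow(bonds)
  if (is.null(atoms$.explicit_h)) atoms$.explicit_h <- integer(na)

  in_ring <- logical(nb)
  if (nb > 0L) {
    gr <- igraph::graph_from_edgelist(
      cbind(bonds$begin, bonds$end), directed = FALSE)
    if (length(igraph::V(gr)) < na)
      gr <- igraph::add_vertices(gr, na - length(igraph::V(gr)))
    br <- igraph::bridges(gr)
    in_ring <- !(seq_len(nb) %in% as.integer(br))
  }

  # resolve bond orders; default bond between two aromatic atoms is aromatic
  # only inside a ring (so biphenyl-style links stay single)
  arom_bond <- logical(nb)
  order <- numeric(nb)
  for (b in seq_len(nb)) {
    sym <- bonds$sym[b]
    both_arom <- atoms$aromatic[bonds$begin[b]] && atoms$aromatic[bonds$end[b]]
    if (sym == ":" || (sym %in% c("", "/", "\\") && both_arom && in_ring[b])) {
      arom_bond[b] <- TRUE
      order[b] <- 1.5
    } else {
      order[b] <- switch(sym, "=" = 2, "#" = 3, 1)  # default/-/\// are single
    }
  }
  if (any(atoms$aromatic)) {
    arom_atom_in_ring <- rep(FALSE, na)
    if (nb > 0L) {
      arom_atom_in_ring[unique(c(bonds$begin[arom_bond], bonds$end[arom_bond]))] <- TRUE
    }
    bad <- which(atoms$aromatic & !arom_atom_in_ring)
    if (length(bad) > 0L)
      stop_parse(id, paste0("aromatic atom(s) outside any aromatic ring: ",
                            paste(bad, collapse = ", ")))
  }

  degree <- integer(na)
  if (nb > 0L) {
    tb <- table(factor(c(bonds$begin, bonds$end), levels = seq_len(na)))
    degree <- as.integer(tb)
  }

  # implicit hydrogens for unbracketed organic-subset atoms
  nH <- integer(na)
  for (a in seq_len(na)) {
    if (atoms$bracket[a]) {
      nH[a] <- atoms$hcount[a]
      next
    }
    el <- atoms$element[a]
    vals <- .ORGANIC_VALENCES[[el]]
    if (is.null(vals)) { nH[a] <- 0L; next }
    inc <- which(bonds$begin == a | bonds$end == a)
    if (atoms$aromatic[a]) {
      bsum <- degree[a] + if (el %in% c("O", "S", "Se")) 0L else 1L
    } else {
      bsum <- sum(order[inc])
    }
    v <- vals[vals >= bsum]
    nH[a] <- if (length(v) == 0L) 0L else as.integer(v[1] - bsum)
  }
  nH <- nH + atoms$.explicit_h * 0L  # explicit H already folded into hcount

  hybrid <- .hybridization(atoms, bonds, order, arom_bond, degree, na)
  conj <- .conjugation(atoms, bonds, order, arom_bond, na)
  stereo <- .bond_stereo(atoms, bonds, order, arom_bond)

  atoms_out <- data.frame(
    element = atoms$element,
    atomic_number = .atomic_number(atoms$element),
    aromatic = atoms$aromatic,
    charge = atoms$charge,
    chirality = ifelse(atoms$chirality == "", "unspecified", atoms$chirality),
    n_hydrogens = nH,
    degree = degree,
    hybridization = hybrid,
    mass = .atomic_mass(atoms$element),
    stringsAsFactors = FALSE)

  bond_type <- ifelse(arom_bond, "aromatic",
                      c("single", "double", "triple")[pmin(order, 3)])
  bonds_out <- data.frame(
    begin = bonds$begin, end = bonds$end,
    order = bond_type,
    aromatic = arom_bond,
    conjugated = conj,
    in_ring = in_ring,
    stereo = stereo,
    stringsAsFactors = FALSE)
  rownames(atoms_out) <- rownames(bonds_out) <- NULL
  list(atoms = atoms_out, bonds = bonds_out)
}

.hybridization <- function(atoms, bonds, order, arom_bond, degree, na) {
  out <- character(na)
  for (a in seq_len(na)) {
    inc <- which(bonds$begin == a | bonds$end == a)
    ords <- order[inc]
    n_triple <- sum(ords == 3)
    n_double <- sum(ords == 2)
    if (degree[a] >= 6L) out[a] <- "sp3d2"
    else if (degree[a] == 5L) out[a] <- "sp3d"
    else if (n_triple >= 1L || n_double >= 2L) out[a] <- "sp"
    else if (n_double == 1L || atoms$aromatic[a] || any(arom_bond[inc]))
      out[a] <- "sp2"
    else out[a] <- "sp3"
  }
  out
}

# A bond is conjugated when it takes part in an extended pi system: aromatic
# bonds always; multiple bonds adjacent to another pi bond or to a lone-pair
# heteroatom; single bonds linking two pi centres (or one pi centre and a
# lone-pair N/O/S). This mirrors the usual toolkit notion closely enough for
# one-hot featurization.
.conjugation <- function(atoms, bonds, order, arom_bond, na) {
  nb <- nrow(bonds)
  if (nb == 0L) return(logical(0))
  haspi <- rep(FALSE, na)
  for (b in seq_len(nb)) {
    if (order[b] >= 2 || arom_bond[b]) {
      haspi[bonds$begin[b]] <- TRUE
      haspi[bonds$end[b]] <- TRUE
    }
  }
  lone <- atoms$element %in% c("N", "O", "S", "P")
  out <- logical(nb)
  for (b in seq_len(nb)) {
    u <- bonds$begin[b]; v <- bonds$end[b]
    if (arom_bond[b]) { out[b] <- TRUE; next }
    if (order[b] >= 2) {
      inc_u <- which((bonds$begin == u | bonds$end == u))
      inc_v <- which((bonds$begin == v | bonds$end == v))
      others <- setdiff(c(inc_u, inc_v), b)
      other_pi <- any(order[others] >= 2 | arom_bond[others])
      nbrs <- setdiff(c(bonds$begin[others], bonds$end[others]), c(u, v))
      out[b] <- other_pi || any(lone[nbrs])
    } else {
      out[b] <- (haspi[u] && (haspi[v] || lone[v])) ||
                (haspi[v] && (haspi[u] || lone[u]))
    }
  }
  out
}

# cis/trans perception from directional single bonds around non-aromatic
# double bonds. side = f(symbol, writing order); equal sides -> cis,
# opposite -> trans (verified against the F/C=C/F trans convention).
.bond_stereo <- function(atoms, bonds, order, arom_bond) {
  nb <- nrow(bonds)
  stereo <- rep("none", nb)
  if (nb == 0L) return(stereo)
  dir <- which(bonds$sym %in% c("/", "\\"))
  if (length(dir) == 0L) return(stereo)
  side_of <- function(b, ref_atom) {
    s <- if (bonds$sym[b] == "/") 1 else -1
    d <- if (bonds$end[b] == ref_atom) 1 else -1  # substituent written first?
    s * d
  }
  for (b in which(order == 2 & !arom_bond)) {
    u <- bonds$begin[b]; v <- bonds$end[b]
    du <- dir[bonds$begin[dir] == u | bonds$end[dir] == u]
    dv <- dir[bonds$begin[dir] == v | bonds$end[dir] == v]
    du <- setdiff(du, b); dv <- setdiff(dv, b)
    if (length(du) >= 1L && length(dv) >= 1L) {
      su <- side_of(du[1], u)
      sv <- side_of(dv[1], v)
      stereo[b] <- if (su == sv) "cis" else "trans"
    }
  }
  stereo
}
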