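#' Read molecules from a SMILES or CSV file
#'
#' `.smi`/`.txt` files hold one `SMILES<TAB>id` (or whitespace-separated)
#' record per line, id optional; CSV files are read with configurable
#' column names.
#'
#' @param path Input file.
#' @param smiles_col,id_col Column names for CSV input (defaults `"smiles"`,
#'   `"id"`; a missing id column yields sequential ids).
#' @return Data frame with columns `id` and `smiles`.
#' @export
read_smiles_file <- function(path, smiles_col = "smiles", id_col = "id") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) {
    df <- utils::read.csv(path, sep = if (ext == "tsv") "\t" else ",",
                          stringsAsFactors = FALSE)
    if (!smiles_col %in% names(df)) {
      stop("column '", smiles_col, "' not found in ", path, call. = FALSE)
    }
    smiles <- as.character(df[[smiles_col]])
    ids <- if (id_col %in% names(df)) as.character(df[[id_col]])
           else sprintf("MOL%05d", seq_along(smiles))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "[\t ]+")
    smiles <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2L) parts[[i]][2L] else sprintf("MOL%05d", i)
    }, "")
  }
  if (length(smiles) == 0L) stop("no molecules in ", path, call. = FALSE)
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Write molecules to a `.smi` file
#'
#' @param mols Data frame with `id` and `smiles` columns.
#' @param path Output path.
#' @export
write_smiles_file <- function(mols, path) {
  writeLines(paste(mols$smiles, mols$id, sep = "\t"), path)
  invisible(path)
}

#' Parse a table of molecules
#'
#' Vectorized [parse_smiles()] over a data frame; parse failures are
#' collected and reported together, naming the offending record ids.
#'
#' @param mols Data frame with `id` and `smiles`.
#' @param canonicalize Passed to [parse_smiles()] (the canonical forms for
#'   the whole set are obtained in one OpenBabel call).
#' @return List of `molecule_record`s.
#' @export
parse_molecules <- function(mols, canonicalize = TRUE) {
  stopifnot(is.data.frame(mols), all(c("id", "smiles") %in% names(mols)))
  records <- vector("list", nrow(mols))
  failures <- character(0)
  for (i in seq_len(nrow(mols))) {
    records[[i]] <- tryCatch(
      parse_smiles(mols$smiles[i], mols$id[i], canonicalize = FALSE),
      error = function(e) {
        failures <<- c(failures, conditionMessage(e))
        NULL
      })
  }
  if (length(failures) > 0L) {
    stop("failed to parse ", length(failures), " record(s):\n  ",
         paste(utils::head(failures, 10L), collapse = "\n  "), call. = FALSE)
  }
  if (isTRUE(canonicalize)) {
    canon <- tryCatch(canonical_smiles(mols$smiles), error = function(e) NULL)
    if (!is.null(canon)) {
      for (i in seq_along(records)) records[[i]]$smiles <- canon[i]
    }
  }
  records
}

# stable content hash of a configuration (for artifact provenance)
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", .hash_ints(utf8ToInt(s)))
}
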