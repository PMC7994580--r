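#' Read a PDB-format structure into an atom tibble
#'
#' Parses ATOM and HETATM records of a fixed-column PDB file. Only the
#' first MODEL of a multi-model file is kept (with a warning). Alternate
#' locations follow the single-conformer convention: atoms with a blank
#' alt-loc or `'A'` are retained, others dropped. Malformed fixed-column
#' records are rejected with the offending line number.
#'
#' @param path Path to a PDB file.
#' @param keep_hetatm Keep HETATM records (default `TRUE`).
#' @return A tibble with one row per atom: `serial`, `atom_name`,
#'   `alt_loc`, `res_name`, `chain`, `res_seq`, `icode`, `x`, `y`, `z`,
#'   `occupancy`, `b_factor`, `element`.
#' @seealso [write_pdb()], [map_entropy_to_bfactors()]
#' @export
read_pdb <- function(path, keep_hetatm = TRUE) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1) {
    warn(sprintf("'%s' has %d models; keeping MODEL 1 only",
                 path, length(model_starts)))
    endmdl <- which(trimws(rec) == "ENDMDL")
    lines <- lines[seq_len(endmdl[1])]
    rec <- substr(lines, 1, 6)
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop_input(sprintf("no ATOM/HETATM records in '%s'", path))
  bad <- which(is_atom & nchar(lines) < 54)
  coords_ok <- function(l) {
    v <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                       substr(l, 47, 54))))
    !anyNA(v)
  }
  bad <- c(bad, which(is_atom)[!vapply(lines[is_atom], coords_ok, logical(1))])
  if (length(bad) > 0) {
    abort(sprintf("malformed ATOM/HETATM record(s) at line(s): %s",
                  paste(sort(unique(bad)), collapse = ", ")),
          class = "calmscape_parse_error")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  # single-conformer alt-loc policy: blank or 'A'
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  out <- tibble::tibble(
    serial = as.integer(at$eleno),
    atom_name = at$elety,
    alt_loc = ifelse(is.na(at$alt), "", at$alt),
    res_name = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    res_seq = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1, 1), trimws(at$elesy))
  )
  key <- paste(out$chain, out$res_seq, out$icode, out$atom_name, out$alt_loc)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate atoms after alt-loc filtering in '%s'", path),
          class = "calmscape_parse_error")
  }
  out
}

#' Write an atom tibble as a fixed-column PDB file
#'
#' Writes ATOM records with the conventional fixed-column layout
#' (coordinates `%8.3f`, occupancy and B-factor `%6.2f`), so B-factors
#' painted with entropies round-trip to two decimals.
#'
#' @param structure Atom tibble as returned by [read_pdb()] or the
#'   structure generators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  structure <- as_structure(structure)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(structure[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(structure)),
    resno = structure$res_seq,
    resid = structure$res_name,
    eleno = structure$serial,
    elety = structure$atom_name,
    chain = structure$chain,
    insert = ifelse(structure$icode == "", NA, structure$icode),
    o = structure$occupancy,
    b = structure$b_factor,
    elesy = structure$element
  )
  invisible(path)
}

# validate/normalise an atom tibble
as_structure <- function(structure) {
  need <- c("atom_name", "res_name", "chain", "res_seq", "x", "y", "z")
  if (!is.data.frame(structure) || !all(need %in% names(structure))) {
    stop_input(sprintf("a structure needs columns: %s",
                       paste(need, collapse = ", ")))
  }
  if (!all(is.finite(structure$x) & is.finite(structure$y) &
           is.finite(structure$z))) {
    stop_input("structure coordinates must be finite")
  }
  structure <- tibble::as_tibble(structure)
  has <- function(col) col %in% names(structure)
  if (!has("serial")) structure$serial <- seq_len(nrow(structure))
  if (!has("alt_loc")) structure$alt_loc <- ""
  if (!has("icode")) structure$icode <- ""
  if (!has("occupancy")) structure$occupancy <- 1
  if (!has("b_factor")) structure$b_factor <- 0
  if (!has("element")) {
    structure$element <- substr(trimws(structure$atom_name), 1, 1)
  }
  structure
}

# residues in order of first appearance
structure_residues <- function(structure) {
  structure |>
    dplyr::distinct(.data$chain, .data$res_seq, .data$icode, .data$res_name)
}

#' One-letter sequence of a structure chain
#'
#' @param structure Atom tibble.
#' @param chain Chain id.
#' @return A tibble with `res_seq`, `icode`, `res_name`, `aa` (one-letter
#'   code, `"X"` for unrecognised residue names), in residue order.
#' @export
structure_sequence <- function(structure, chain) {
  structure <- as_structure(structure)
  res <- structure_residues(structure[structure$chain == chain, ])
  if (nrow(res) == 0) {
    abort(sprintf("chain '%s' not present in structure", chain),
          class = "calmscape_selection_error")
  }
  res$aa <- dplyr::coalesce(unname(AA_ONE[res$res_name]), "X")
  dplyr::select(res, "res_seq", "icode", "res_name", "aa")
}
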