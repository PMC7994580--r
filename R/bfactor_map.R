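#' Residue correspondences between alignment columns and structure residues
#'
#' Conservation painting needs to know which alignment column belongs to
#' which structure residue. `correspondence_from_numbering()` assumes
#' column *j* maps to residue `j + offset` of one chain (adequate when the
#' structure is numbered along the alignment).
#' `correspondence_from_sequence()` derives the mapping by globally
#' aligning the chain's one-letter sequence against a chosen alignment row
#' (BLOSUM62); alignment gaps leave residues unmapped.
#'
#' @param structure Atom tibble (see [read_pdb()]).
#' @param chain Chain id to map.
#' @param n_columns Number of alignment columns available.
#' @param offset Residue number of the residue matching column 1, minus 1.
#' @return A tibble with columns `column`, `chain`, `res_seq`, `icode`;
#'   each structure residue appears at most once.
#' @export
correspondence_from_numbering <- function(structure, chain, n_columns,
                                          offset = 0) {
  structure <- as_structure(structure)
  res <- structure_sequence(structure, chain)
  out <- tibble::tibble(column = res$res_seq - offset, chain = chain,
                        res_seq = res$res_seq, icode = res$icode)
  dplyr::filter(out, .data$column >= 1, .data$column <= n_columns)
}

#' @rdname correspondence_from_numbering
#' @param aln Alignment tibble (`id`, `seq`).
#' @param row_id Id of the alignment row the chain corresponds to.
#' @export
correspondence_from_sequence <- function(structure, chain, aln, row_id) {
  structure <- as_structure(structure)
  res <- structure_sequence(structure, chain)
  row <- aln$seq[aln$id == row_id]
  if (length(row) != 1) {
    stop_input(sprintf("row id '%s' not found in alignment", row_id))
  }
  row <- toupper(row)
  row_cols <- which(chars(row) != "-")  # alignment column of each residue
  row_ungapped <- gsub("-", "", row, fixed = TRUE)
  struct_seq <- paste0(res$aa, collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    pattern = struct_seq, subject = row_ungapped, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  p_chars <- chars(as.character(Biostrings::alignedPattern(pa)))
  s_chars <- chars(as.character(Biostrings::alignedSubject(pa)))
  pi <- 0L; si <- 0L
  pairs <- vector("list", length(p_chars))
  for (k in seq_along(p_chars)) {
    if (p_chars[k] != "-") pi <- pi + 1L
    if (s_chars[k] != "-") si <- si + 1L
    if (p_chars[k] != "-" && s_chars[k] != "-") {
      pairs[[k]] <- c(pi, si)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    return(tibble::tibble(column = integer(), chain = character(),
                          res_seq = integer(), icode = character()))
  }
  tibble::tibble(
    column = row_cols[pairs[, 2]],
    chain = chain,
    res_seq = res$res_seq[pairs[, 1]],
    icode = res$icode[pairs[, 1]]
  )
}

#' Paint per-column entropies onto structure B-factors
#'
#' Replaces the B-factor of every atom of each mapped residue with the
#' Shannon entropy (bits) of its alignment column, so that molecular
#' viewers can colour the protein surface by conservation. Residues not
#' covered by the correspondence (and residues mapped to columns with
#' undefined entropy) receive the `sentinel` value, which is visually
#' distinct and survives the `%6.2f` PDB field.
#'
#' @param structure Atom tibble.
#' @param profile Entropy profile from [entropy_profile()].
#' @param correspondence Tibble with `column`, `chain`, `res_seq`,
#'   `icode`, e.g. from [correspondence_from_sequence()].
#' @param sentinel B-factor for unmapped residues (default 99.99).
#' @return The painted atom tibble, with attributes `n_mapped` and
#'   `n_unmapped` (residue counts over the whole structure).
#' @examples
#' sim <- simulate_msa(10, 5, 1, seed = 1)
#' prof <- entropy_profile(sim$alignment)
#' pair <- simulate_structure_pair(5, seed = 1)
#' corr <- correspondence_from_numbering(pair$a, "A", nrow(prof))
#' painted <- map_entropy_to_bfactors(pair$a, prof, corr)
#' unique(painted$b_factor)   # all 0: fully conserved columns
#' @export
map_entropy_to_bfactors <- function(structure, profile, correspondence,
                                    sentinel = 99.99) {
  structure <- as_structure(structure)
  corr <- correspondence
  need <- c("column", "chain", "res_seq", "icode")
  if (!is.data.frame(corr) || !all(need %in% names(corr))) {
    stop_input("`correspondence` needs columns: column, chain, res_seq, icode")
  }
  if (any(corr$column < 1 | corr$column > nrow(profile))) {
    abort("correspondence columns outside profile range",
          class = "calmscape_mapping_error")
  }
  res_key <- function(chain, res_seq, icode) paste(chain, res_seq, icode)
  struct_keys <- res_key(structure$chain, structure$res_seq, structure$icode)
  corr_keys <- res_key(corr$chain, corr$res_seq, corr$icode)
  if (anyDuplicated(corr_keys)) {
    abort("a structure residue is mapped to more than one column",
          class = "calmscape_mapping_error")
  }
  missing <- setdiff(corr_keys, struct_keys)
  if (length(missing) > 0) {
    abort(sprintf("correspondence names residues absent from the structure: %s",
                  paste(missing, collapse = "; ")),
          class = "calmscape_mapping_error")
  }
  h <- profile$H[corr$column]
  b_by_res <- stats::setNames(ifelse(is.na(h), sentinel, h), corr_keys)
  new_b <- unname(b_by_res[struct_keys])
  structure$b_factor <- ifelse(is.na(new_b), sentinel, new_b)
  n_res_total <- nrow(structure_residues(structure))
  n_mapped <- length(unique(struct_keys[struct_keys %in% corr_keys[!is.na(h)]]))
  attr(structure, "n_mapped") <- n_mapped
  attr(structure, "n_unmapped") <- n_res_total - n_mapped
  structure
}

#' Flag strictly conserved residues from entropy-painted B-factors
#'
#' After [map_entropy_to_bfactors()], classifies each residue as
#' conserved iff its entropy B-factor is strictly below `cap` (default
#' 0.3 bits, i.e. roughly 97% identity). Sentinel-valued (unmapped)
#' residues are excluded and reported, never classified.
#'
#' @param structure Entropy-painted atom tibble.
#' @param cap Conservation cap in bits; strict `<` comparison.
#' @param sentinel Sentinel value used for unmapped residues.
#' @return A tibble with one row per residue: `chain`, `res_seq`,
#'   `icode`, `res_name`, `H`, `conserved`, `excluded`; attribute
#'   `n_conserved` holds the summary count.
#' @export
classify_conserved <- function(structure, cap = 0.3, sentinel = 99.99) {
  structure <- as_structure(structure)
  res <- structure |>
    dplyr::group_by(.data$chain, .data$res_seq, .data$icode, .data$res_name) |>
    dplyr::summarise(H = .data$b_factor[1], .groups = "drop")
  res$excluded <- res$H == sentinel
  res$conserved <- !res$excluded & res$H < cap
  res$H[res$excluded] <- NA_real_
  if (all(res$excluded)) {
    warn("no residues carry entropy values (all sentinel); nothing classified")
  }
  attr(res, "n_conserved") <- sum(res$conserved)
  attr(res, "n_excluded") <- sum(res$excluded)
  res
}
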