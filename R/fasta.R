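#' Read a protein multiple sequence alignment from aligned FASTA
#'
#' Reads an aligned FASTA file into a tibble with one row per sequence.
#' Rows are uppercased and `'.'` gap characters are normalised to `'-'`.
#' Records of unequal length, duplicate identifiers and empty files are
#' rejected.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id` (character, unique) and `seq`
#'   (character, all the same width).
#' @seealso [entropy_profile()], [write_fasta()]
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_input(
                    sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0) stop_input(sprintf("no FASTA records in '%s'", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_input(sprintf("duplicate sequence ids: %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  rows <- toupper(chartr(".", "-", as.character(set)))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    abort(sprintf("alignment rows have unequal lengths (%s)",
                  paste(sort(unique(widths)), collapse = ", ")),
          class = "calmscape_alignment_error")
  }
  tibble::tibble(id = ids, seq = unname(rows))
}

#' Write sequences to FASTA
#'
#' @param seqs A data frame with columns `id` and `seq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(stats::setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# alignment tibble -> character matrix (rows x columns)
aln_matrix <- function(aln) {
  stopifnot(is.data.frame(aln), all(c("id", "seq") %in% names(aln)),
            nrow(aln) >= 1)
  w <- unique(nchar(aln$seq))
  if (length(w) != 1) {
    abort("alignment rows have unequal lengths",
          class = "calmscape_alignment_error")
  }
  m <- matrix(unlist(strsplit(toupper(aln$seq), "", fixed = TRUE)),
              nrow = nrow(aln), byrow = TRUE)
  rownames(m) <- aln$id
  m
}
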