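# Small in-code fixtures shared across test files.

# counts for a column following the majority-p family over N sequences
majority_counts <- function(p, N = 100, majority = "A") {
  others <- setdiff(AA_ALPHABET, majority)
  stats::setNames(c(p * N, rep((1 - p) * N / 19, 19)), c(majority, others))
}

# write an alignment tibble to a temporary FASTA file
tmp_fasta <- function(aln) {
  f <- tempfile(fileext = ".fasta")
  write_fasta(aln, f)
  f
}

# a straight CA-only chain with chosen residue names, 3.8 A spacing
ca_chain <- function(res_names, chain = "A") {
  n <- length(res_names)
  tibble::tibble(
    serial = seq_len(n), atom_name = "CA", alt_loc = "",
    res_name = res_names, chain = chain, res_seq = seq_len(n), icode = "",
    x = 3.8 * (seq_len(n) - 1), y = 0, z = 0,
    occupancy = 1, b_factor = 0, element = "C"
  )
}

# extract the planted instances of one segment from a split-motif sim
planted_instances <- function(sim, segment) {
  st <- sim$truth[[paste0("seg", segment, "_start")]]
  w <- sim$segment_widths[segment]
  seqs <- sim$sequences$seq[match(sim$truth$id, sim$sequences$id)]
  substring(seqs, st, st + w - 1)
}

# split-motif model built from a simulation's own planted instances
model_from_sim <- function(sim) {
  segs <- lapply(1:3, function(k) build_pssm(planted_instances(sim, k)))
  split_motif_model(segs, sim$spacer_ranges)
}
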