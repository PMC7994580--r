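#' Pipeline runs: conservation painting, structure comparison, interface
#'
#' These wrappers chain the analysis stages end to end on files, write
#' their outputs under `out_dir` with fixed names, and record a manifest
#' (`manifest.json`: input file hashes, every parameter value, package
#' version) so a run can be audited and repeated; reruns with identical
#' inputs produce byte-identical outputs.
#'
#' * `run_entropy_map()`: alignment + structure -> entropy profile TSV
#'   (`profile.tsv`), entropy-painted PDB (`painted.pdb`) and a summary
#'   (`summary.json`) with the conserved-residue count at the cap.
#' * `run_compare()`: two structures -> superposition report
#'   (`report.json`), transformed mobile structure (`superposed.pdb`) and
#'   structure-based sequence alignment (`alignment.fasta`).
#' * `run_interface()`: a complex -> interface report (`interface.json`)
#'   and hydrophobic patch table (`patches.tsv`).
#'
#' @param aln_path Aligned FASTA path.
#' @param pdb_path,ref_path,mob_path PDB file paths.
#' @param chain,chain_ref,chain_mob,chains Chain selections.
#' @param row_id Alignment row matching the structure chain; default the
#'   first row.
#' @param cap Conservation cap in bits (default 0.3).
#' @param selection,max_cycles,reject_factor,pair_cutoff See
#'   [superpose()] and [structure_alignment()].
#' @param delta_threshold,scheme,exposure_cutoff,adjacency_cutoff See
#'   [interface_bsa()] and [hydrophobic_patches()].
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly; outputs land in files.
#' @name pipeline
NULL

write_manifest <- function(out_dir, command, inputs, params) {
  manifest <- list(
    command = command,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    parameters = params,
    package = "calmscape",
    version = as.character(utils::packageVersion("calmscape"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' @rdname pipeline
#' @export
run_entropy_map <- function(aln_path, pdb_path, chain, row_id = NULL,
                            cap = 0.3, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_alignment(aln_path)
  model <- read_pdb(pdb_path)
  row_id <- row_id %||% aln$id[1]
  profile <- entropy_profile(aln, cap = cap)
  corr <- correspondence_from_sequence(model, chain, aln, row_id)
  painted <- map_entropy_to_bfactors(model, profile, corr)
  flags <- classify_conserved(painted, cap = cap)
  write_profile_tsv(profile, file.path(out_dir, "profile.tsv"))
  write_pdb(painted, file.path(out_dir, "painted.pdb"))
  jsonlite::write_json(list(
    n_columns = nrow(profile),
    n_residues_mapped = attr(painted, "n_mapped"),
    n_residues_unmapped = attr(painted, "n_unmapped"),
    n_conserved = attr(flags, "n_conserved"),
    cap = cap
  ), file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "entropy-map",
                 list(alignment = aln_path, structure = pdb_path),
                 list(chain = chain, row_id = row_id, cap = cap))
  invisible(out_dir)
}

#' @rdname pipeline
#' @export
run_compare <- function(mob_path, ref_path, chain_mob = NULL,
                        chain_ref = NULL,
                        selection = "backbone", max_cycles = 5,
                        reject_factor = 2, pair_cutoff = 4,
                        out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mob <- read_pdb(mob_path)
  ref <- read_pdb(ref_path)
  chain_mob <- chain_mob %||% mob$chain[1]
  chain_ref <- chain_ref %||% ref$chain[1]
  if (!any(mob$chain == chain_mob)) {
    abort(sprintf("chain '%s' not present in %s", chain_mob, mob_path),
          class = "calmscape_selection_error")
  }
  if (!any(ref$chain == chain_ref)) {
    abort(sprintf("chain '%s' not present in %s", chain_ref, ref_path),
          class = "calmscape_selection_error")
  }
  fit <- superpose(mob[mob$chain == chain_mob, ],
                   ref[ref$chain == chain_ref, ],
                   selection = selection, max_cycles = max_cycles,
                   reject_factor = reject_factor)
  aln <- structure_alignment(mob, ref, fit, chain_mob, chain_ref,
                             pair_cutoff = pair_cutoff)
  write_pdb(apply_transform(mob, fit), file.path(out_dir, "superposed.pdb"))
  jsonlite::write_json(list(
    rmsd = fit$rmsd, n_retained = fit$n_retained, n_input = fit$n_input,
    cycles_run = fit$cycles_run, selection = selection,
    rejected_residues = as.list(fit$rejected_residues),
    n_aligned_residues = nrow(aln$pairs)
  ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_fasta(tibble::tibble(
    id = c(sprintf("mobile_%s", chain_mob), sprintf("reference_%s", chain_ref)),
    seq = unname(aln$alignment)),
    file.path(out_dir, "alignment.fasta"))
  write_manifest(out_dir, "superpose",
                 list(mobile = mob_path, reference = ref_path),
                 list(chain_mob = chain_mob, chain_ref = chain_ref,
                      selection = selection, max_cycles = max_cycles,
                      reject_factor = reject_factor,
                      pair_cutoff = pair_cutoff))
  invisible(out_dir)
}

#' @rdname pipeline
#' @export
run_interface <- function(pdb_path, chains, delta_threshold = 1,
                          scheme = "phi", exposure_cutoff = 0.05,
                          adjacency_cutoff = 4.5, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(chains) != 2) stop_input("`chains` must name two chains")
  model <- read_pdb(pdb_path)
  rep <- interface_bsa(model, chains[1], chains[2],
                       delta_threshold = delta_threshold, scheme = scheme)
  patches <- dplyr::bind_rows(lapply(chains, function(ch) {
    p <- hydrophobic_patches(model, chain = ch, scheme = scheme,
                             exposure_cutoff = exposure_cutoff,
                             adjacency_cutoff = adjacency_cutoff)
    if (nrow(p) > 0) dplyr::mutate(p, chain = ch, .before = 1) else NULL
  }))
  jsonlite::write_json(list(
    bsa = rep$bsa,
    n_interface = sum(rep$residues$interface),
    hydrophobic_fraction = rep$hydrophobic_fraction,
    residues = rep$residues
  ), file.path(out_dir, "interface.json"), auto_unbox = TRUE, digits = NA)
  if (nrow(patches) > 0) {
    patches$residues <- vapply(patches$residues, paste, character(1),
                               collapse = ",")
  }
  utils::write.table(as.data.frame(patches),
                     file.path(out_dir, "patches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "interface", list(structure = pdb_path),
                 list(chains = paste(chains, collapse = ","),
                      delta_threshold = delta_threshold, scheme = scheme,
                      exposure_cutoff = exposure_cutoff,
                      adjacency_cutoff = adjacency_cutoff))
  invisible(out_dir)
}
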