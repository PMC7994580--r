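#' Simulate a protein multiple sequence alignment with known column truth
#'
#' Generates an alignment whose columns follow the "majority residue plus
#' uniform remainder" model that underlies per-site conservation analysis:
#' in column *j* a (randomly chosen) majority residue appears with
#' probability `column_identity[j]` and each of the other 19 amino acids
#' with the remaining mass split evenly. Gaps are introduced independently
#' per cell at `gap_rate`. The majority residue per column is recorded as
#' ground truth so downstream entropy estimates can be checked against the
#' analytic value.
#'
#' @param n_sequences Number of rows.
#' @param length Number of columns.
#' @param column_identity Majority-residue frequency per column, a single
#'   fraction or a vector of `length` fractions, each in `[1/20, 1]`.
#' @param gap_rate Per-cell gap probability in `[0, 1)`.
#' @param seed Integer seed; the call uses its own RNG stream.
#' @return A list with `alignment` (tibble `id`, `seq`) and `truth`
#'   (tibble `column`, `majority`, `identity`).
#' @examples
#' sim <- simulate_msa(83, 10, column_identity = 0.97, seed = 1)
#' entropy_profile(sim$alignment)
#' @export
simulate_msa <- function(n_sequences, length, column_identity,
                         gap_rate = 0, seed = 1) {
  n_sequences <- check_count(n_sequences, "n_sequences")
  length <- check_count(length, "length")
  if (!(base::length(column_identity) %in% c(1L, length))) {
    stop_spec("`column_identity` must have length 1 or `length`")
  }
  check_fraction(column_identity, "column_identity", lo = 1 / 20, hi = 1)
  check_fraction(gap_rate, "gap_rate", hi = 1, hi_open = TRUE)
  p <- rep_len(column_identity, length)
  with_seed(seed, {
    majority <- sample(AA_ALPHABET, length, replace = TRUE)
    m <- matrix("", nrow = n_sequences, ncol = length)
    for (j in seq_len(length)) {
      is_maj <- stats::runif(n_sequences) < p[j]
      others <- setdiff(AA_ALPHABET, majority[j])
      m[, j] <- ifelse(is_maj, majority[j],
                       sample(others, n_sequences, replace = TRUE))
    }
    if (gap_rate > 0) {
      m[matrix(stats::runif(n_sequences * length) < gap_rate,
               nrow = n_sequences)] <- "-"
    }
    list(
      alignment = tibble::tibble(
        id = sprintf("seq%04d", seq_len(n_sequences)),
        seq = apply(m, 1, paste0, collapse = "")
      ),
      truth = tibble::tibble(column = seq_len(length),
                             majority = majority, identity = p)
    )
  })
}

# rotation matrix from axis-angle (Rodrigues' formula)
rotation_from_axis_angle <- function(axis, angle) {
  nrm <- sqrt(sum(axis^2))
  if (!is.numeric(axis) || base::length(axis) != 3 || nrm < 1e-12) {
    stop_spec("`axis` must be a non-zero length-3 vector")
  }
  u <- axis / nrm
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# idealised backbone chain: CA along an alpha-helical curve with 3.8 A
# CA-CA spacing, plus N, C, O placed in the local frame of each residue
build_backbone_chain <- function(n_residues, chain_id = "A",
                                 res_names = NULL) {
  i <- seq_len(n_residues)
  theta <- (i - 1) * (100 * pi / 180)
  raw <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
  step <- sqrt(sum((raw[2, ] - raw[1, ])^2))
  ca <- raw * (3.8 / step)
  if (is.null(res_names)) res_names <- rep("ALA", n_residues)
  rows <- vector("list", n_residues)
  for (k in i) {
    nxt <- if (k < n_residues) ca[k + 1, ] - ca[k, ] else ca[k, ] - ca[k - 1, ]
    u <- nxt / sqrt(sum(nxt^2))
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    nvec <- c(u[2] * ref[3] - u[3] * ref[2],
              u[3] * ref[1] - u[1] * ref[3],
              u[1] * ref[2] - u[2] * ref[1])
    nvec <- nvec / sqrt(sum(nvec^2))
    bvec <- c(u[2] * nvec[3] - u[3] * nvec[2],
              u[3] * nvec[1] - u[1] * nvec[3],
              u[1] * nvec[2] - u[2] * nvec[1])
    pos <- rbind(N = ca[k, ] - 0.9 * u + 1.1 * nvec,
                 CA = ca[k, ],
                 C = ca[k, ] + 0.9 * u - 1.1 * nvec,
                 O = ca[k, ] + 0.9 * u - 1.1 * nvec + 1.23 * bvec)
    rows[[k]] <- tibble::tibble(
      atom_name = c("N", "CA", "C", "O"),
      res_name = res_names[k], chain = chain_id, res_seq = k,
      x = unname(pos[, 1]), y = unname(pos[, 2]), z = unname(pos[, 3]),
      element = c("N", "C", "C", "O")
    )
  }
  d <- dplyr::bind_rows(rows)
  tibble::tibble(
    serial = seq_len(nrow(d)), atom_name = d$atom_name, alt_loc = "",
    res_name = d$res_name, chain = d$chain, res_seq = d$res_seq,
    icode = "", x = d$x, y = d$y, z = d$z,
    occupancy = 1, b_factor = 0, element = d$element
  )
}

#' Simulate a structure pair related by a known rigid transform
#'
#' Builds an idealised backbone chain A (atoms N, CA, C, O; CA-CA spacing
#' 3.8 angstrom) and its partner `B = R A + t` plus optional Gaussian
#' coordinate noise, with `n_outliers` randomly chosen residues displaced
#' by an additional `outlier_displacement` angstrom in a random direction.
#' The applied rotation, translation and outlier residue numbers are
#' returned as ground truth, so superposition and outlier rejection can be
#' validated exactly.
#'
#' @param n_residues Chain length.
#' @param axis,angle Rotation axis (length-3, non-zero) and angle in
#'   radians.
#' @param translation Length-3 translation vector (angstrom).
#' @param noise_sd Per-coordinate Gaussian noise s.d. (angstrom), `>= 0`.
#' @param n_outliers Number of displaced residues, `< n_residues`.
#' @param outlier_displacement Displacement magnitude (angstrom).
#' @param seed Integer seed.
#' @return A list with structure tibbles `a` and `b` (see [read_pdb()]
#'   for the column layout) and `truth` (`rotation`, `translation`,
#'   `outlier_residues`).
#' @examples
#' pair <- simulate_structure_pair(20, angle = pi / 3, seed = 1)
#' superpose(pair$a, pair$b)
#' @export
simulate_structure_pair <- function(n_residues, axis = c(0, 0, 1),
                                    angle = 0, translation = c(0, 0, 0),
                                    noise_sd = 0, n_outliers = 0,
                                    outlier_displacement = 0, seed = 1) {
  n_residues <- check_count(n_residues, "n_residues", min = 3)
  n_outliers <- check_count(n_outliers, "n_outliers", min = 0)
  if (n_outliers >= n_residues) stop_spec("`n_outliers` must be < `n_residues`")
  if (noise_sd < 0) stop_spec("`noise_sd` must be >= 0")
  R <- rotation_from_axis_angle(axis, angle)
  with_seed(seed, {
    res_names <- sample(unname(AA_THREE), n_residues, replace = TRUE)
    a <- build_backbone_chain(n_residues, "A", res_names)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    b_xyz <- xyz %*% t(R) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
    if (noise_sd > 0) {
      b_xyz <- b_xyz + matrix(stats::rnorm(base::length(b_xyz), sd = noise_sd),
                              ncol = 3)
    }
    outlier_res <- sort(sample(n_residues, n_outliers))
    for (r in outlier_res) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      sel <- a$res_seq == r
      b_xyz[sel, ] <- b_xyz[sel, ] +
        matrix(dir * outlier_displacement, sum(sel), 3, byrow = TRUE)
    }
    b <- a
    b$x <- b_xyz[, 1]; b$y <- b_xyz[, 2]; b$z <- b_xyz[, 3]
    list(a = a, b = b,
         truth = list(rotation = R, translation = translation,
                      outlier_residues = outlier_res))
  })
}

#' Simulate a motif-bearing sequence set with planted split-motif copies
#'
#' Plants `copies_per_sequence` instances of a three-segment split motif
#' into uniform-background protein sequences. Each instance is the segment
#' consensus with per-position substitution: a position matches the
#' consensus with probability `conservation`, otherwise it is replaced by
#' one of the other 19 amino acids uniformly. Segments are separated by
#' spacers drawn uniformly from `spacer_ranges`; instance locations are
#' recorded as ground truth. The first segment's consensus is biased
#' towards aromatic residues (Y/F/W), mirroring the aromatic-rich leading
#' segment typical of CALM repeats.
#'
#' @param copies_per_sequence Copies planted per sequence, in `[0, 5]`.
#' @param n_sequences Number of sequences.
#' @param background_length Sequence length before planting (all sequences
#'   have exactly this length; motif instances overwrite background).
#' @param conservation Per-position consensus match probability in
#'   `(0, 1]`.
#' @param segment_widths Three positive segment widths.
#' @param spacer_ranges List of two `(min, max)` integer pairs for the two
#'   inter-segment spacers.
#' @param seed Integer seed.
#' @return A list with `sequences` (tibble `id`, `seq`), `truth` (tibble
#'   `id`, `copy`, `start`, `end`, `seg1_start`, `seg2_start`,
#'   `seg3_start`, `spacer1`, `spacer2`; 1-based inclusive) and
#'   `consensus` (character vector of the three segment consensi).
#' @examples
#' sim <- simulate_split_motifs(copies_per_sequence = 2, n_sequences = 3,
#'                              background_length = 200,
#'                              conservation = 1, seed = 1)
#' sim$truth
#' @export
simulate_split_motifs <- function(copies_per_sequence, n_sequences,
                                  background_length, conservation,
                                  segment_widths = c(9, 13, 10),
                                  spacer_ranges = list(c(3, 8), c(4, 9)),
                                  seed = 1) {
  n_sequences <- check_count(n_sequences, "n_sequences")
  background_length <- check_count(background_length, "background_length")
  copies_per_sequence <- check_count(copies_per_sequence,
                                     "copies_per_sequence", min = 0)
  if (copies_per_sequence > 5) stop_spec("`copies_per_sequence` must be <= 5")
  check_fraction(conservation, "conservation", lo = 0, hi = 1, lo_open = TRUE)
  if (base::length(segment_widths) != 3 || any(segment_widths < 1)) {
    stop_spec("`segment_widths` must be three positive integers")
  }
  if (base::length(spacer_ranges) != 2 ||
      any(vapply(spacer_ranges, function(r) {
        base::length(r) != 2 || any(r < 0) || r[1] > r[2]
      }, logical(1)))) {
    stop_spec("`spacer_ranges` must be two (min, max) pairs with min <= max")
  }
  max_span <- sum(segment_widths) + spacer_ranges[[1]][2] + spacer_ranges[[2]][2]
  if (copies_per_sequence * max_span > background_length) {
    stop_spec(sprintf(
      "planted span overflow: %d copies of up to %d residues exceed background_length %d",
      copies_per_sequence, max_span, background_length))
  }
  with_seed(seed, {
    aromatic_w <- ifelse(AA_ALPHABET %in% c("Y", "F", "W"), 5, 1)
    consensus <- list(
      paste0(sample(AA_ALPHABET, segment_widths[1], TRUE, prob = aromatic_w),
             collapse = ""),
      paste0(sample(AA_ALPHABET, segment_widths[2], TRUE), collapse = ""),
      paste0(sample(AA_ALPHABET, segment_widths[3], TRUE), collapse = "")
    )
    cons_chars <- lapply(consensus, chars)
    mutate_instance <- function(cs) {
      hit <- stats::runif(base::length(cs)) < conservation
      out <- cs
      for (k in which(!hit)) out[k] <- sample(setdiff(AA_ALPHABET, cs[k]), 1)
      out
    }
    seqs <- character(n_sequences)
    truth <- vector("list", n_sequences)
    for (s in seq_len(n_sequences)) {
      bg <- sample(AA_ALPHABET, background_length, replace = TRUE)
      if (copies_per_sequence > 0) {
        # draw from the range safely (sample() would expand a scalar)
        draw_spacer <- function(r) {
          v <- r[1]:r[2]
          v[sample.int(length(v), copies_per_sequence, replace = TRUE)]
        }
        sp1 <- draw_spacer(spacer_ranges[[1]])
        sp2 <- draw_spacer(spacer_ranges[[2]])
        spans <- sum(segment_widths) + sp1 + sp2
        slack <- background_length - sum(spans)
        gaps <- as.vector(stats::rmultinom(1, slack,
                                           rep(1, copies_per_sequence + 1)))
        starts <- cumsum(c(gaps[1] + 1,
                           if (copies_per_sequence > 1)
                             spans[-copies_per_sequence] +
                               gaps[2:copies_per_sequence]))
        rec <- vector("list", copies_per_sequence)
        for (cp in seq_len(copies_per_sequence)) {
          s1 <- starts[cp]
          s2 <- s1 + segment_widths[1] + sp1[cp]
          s3 <- s2 + segment_widths[2] + sp2[cp]
          bg[s1:(s1 + segment_widths[1] - 1)] <- mutate_instance(cons_chars[[1]])
          bg[s2:(s2 + segment_widths[2] - 1)] <- mutate_instance(cons_chars[[2]])
          bg[s3:(s3 + segment_widths[3] - 1)] <- mutate_instance(cons_chars[[3]])
          rec[[cp]] <- tibble::tibble(
            copy = cp, start = s1, end = s3 + segment_widths[3] - 1,
            seg1_start = s1, seg2_start = s2, seg3_start = s3,
            spacer1 = sp1[cp], spacer2 = sp2[cp])
        }
        truth[[s]] <- dplyr::bind_rows(rec)
      } else {
        truth[[s]] <- tibble::tibble(copy = integer(), start = integer(),
                                     end = integer(), seg1_start = integer(),
                                     seg2_start = integer(),
                                     seg3_start = integer(),
                                     spacer1 = integer(), spacer2 = integer())
      }
      seqs[s] <- paste0(bg, collapse = "")
    }
    ids <- sprintf("prot%03d", seq_len(n_sequences))
    truth_tbl <- dplyr::bind_rows(
      purrr::map2(ids, truth, ~ dplyr::mutate(.y, id = .x, .before = 1)))
    list(sequences = tibble::tibble(id = ids, seq = seqs),
         truth = truth_tbl, consensus = unlist(consensus),
         segment_widths = segment_widths, spacer_ranges = spacer_ranges)
  })
}

#' Simulate a two-chain complex with a planar interface
#'
#' Builds two flat C-alpha sheets facing each other across a plane: chain
#' A at `z = 0` and chain B at `z = interface_spacing`, each residue a
#' single carbon atom on a 3.8-angstrom grid. Residue identities at the
#' interface are hydrophobic with probability
#' `hydrophobic_fraction_at_interface`, recorded as ground truth. With a
#' large spacing (e.g. 100 angstrom) the chains do not contact and the
#' buried surface area is zero; at small spacings (~4 angstrom) a planar
#' interface forms.
#'
#' @param chain_sizes Two positive integers, residues per chain.
#' @param interface_spacing Distance between the chain planes (angstrom),
#'   `> 0`.
#' @param hydrophobic_fraction_at_interface Fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `structure` (atom tibble, chains "A" and "B") and
#'   `truth` (tibble `chain`, `res_seq`, `hydrophobic`).
#' @examples
#' cx <- simulate_complex(c(25, 25), interface_spacing = 4,
#'                        hydrophobic_fraction_at_interface = 1, seed = 1)
#' interface_bsa(cx$structure, "A", "B")$bsa
#' @export
simulate_complex <- function(chain_sizes = c(36, 36), interface_spacing = 4,
                             hydrophobic_fraction_at_interface = 0.7,
                             seed = 1) {
  if (base::length(chain_sizes) != 2) stop_spec("`chain_sizes` must have length 2")
  chain_sizes <- c(check_count(chain_sizes[1], "chain_sizes[1]"),
                   check_count(chain_sizes[2], "chain_sizes[2]"))
  if (interface_spacing <= 0) stop_spec("`interface_spacing` must be > 0")
  check_fraction(hydrophobic_fraction_at_interface,
                 "hydrophobic_fraction_at_interface")
  hydro_res <- c("LEU", "VAL", "ILE", "PHE", "MET", "ALA")
  polar_res <- c("SER", "THR", "ASN", "GLN", "GLU", "LYS", "ASP", "ARG")
  with_seed(seed, {
    build_sheet <- function(n, chain_id, z, xy_offset) {
      side <- ceiling(sqrt(n))
      idx <- seq_len(n) - 1
      hydro <- stats::runif(n) < hydrophobic_fraction_at_interface
      res <- ifelse(hydro, sample(hydro_res, n, TRUE),
                    sample(polar_res, n, TRUE))
      tibble::tibble(
        atom_name = "CA", alt_loc = "", res_name = res, chain = chain_id,
        res_seq = seq_len(n), icode = "",
        x = (idx %% side) * 3.8 + xy_offset,
        y = (idx %/% side) * 3.8 + xy_offset,
        z = z, occupancy = 1, b_factor = 0, element = "C",
        hydrophobic = hydro)
    }
    a <- build_sheet(chain_sizes[1], "A", 0, 0)
    b <- build_sheet(chain_sizes[2], "B", interface_spacing, 1.9)
    both <- dplyr::bind_rows(a, b)
    structure_tbl <- dplyr::mutate(
      dplyr::select(both, -"hydrophobic"),
      serial = dplyr::row_number(), .before = 1)
    list(structure = structure_tbl,
         truth = dplyr::select(both, "chain", "res_seq", "hydrophobic"))
  })
}
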