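#' Solvent-accessible surface area (Shrake–Rupley)
#'
#' Computes per-atom SASA by sphere sampling: each atom is expanded by the
#' probe radius and covered with a deterministic Fibonacci lattice of
#' `n_points` test points; a point is buried when it lies strictly inside
#' any neighbouring expanded sphere (a point exactly on a neighbour's
#' surface counts as accessible). Hydrogens are excluded by default, as
#' crystallographic and cryo-EM models typically omit them.
#'
#' @param structure Atom tibble (see [read_pdb()]).
#' @param probe Probe radius in angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sample points per atom (default 960).
#' @param radii Named element-radius vector with a `.default` fallback;
#'   see [VDW_RADII]. An element absent from a table without `.default`
#'   is a parameter error.
#' @param include_hydrogens Include H atoms (default `FALSE`).
#' @return The atom tibble with an added `sasa` column (square angstrom);
#'   attributes `probe`, `n_points` and `radii` record the
#'   parameterisation. Excluded hydrogens are dropped from the result.
#' @examples
#' one_c <- tibble::tibble(atom_name = "CA", res_name = "ALA", chain = "A",
#'                         res_seq = 1, x = 0, y = 0, z = 0, element = "C")
#' sum(sasa(one_c)$sasa)          # ~ 4 * pi * (1.7 + 1.4)^2
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960,
                 radii = VDW_RADII, include_hydrogens = FALSE) {
  structure <- as_structure(structure)
  if (probe < 0) stop_input("`probe` must be >= 0")
  n_points <- check_count(n_points, "n_points")
  if (!include_hydrogens) {
    structure <- structure[!(toupper(structure$element) %in% c("H", "D")), ]
  }
  if (nrow(structure) == 0) stop_input("no atoms left to compute SASA on")
  el <- toupper(structure$element)
  r <- unname(radii[el])
  if (anyNA(r)) {
    if (".default" %in% names(radii)) {
      r[is.na(r)] <- radii[[".default"]]
    } else {
      abort(sprintf("no radius for element(s): %s",
                    paste(unique(el[is.na(r)]), collapse = ", ")),
            class = "calmscape_parameter_error")
    }
  }
  sphere <- fibonacci_sphere(n_points)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  n <- nrow(xyz)
  rr <- r + probe
  out <- numeric(n)
  # pairwise distances once; neighbour lists per atom
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    if (length(nbr) == 0) {
      out[i] <- 4 * pi * rr[i]^2
      next
    }
    pts <- sphere * rr[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nbr) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 >= rr[j]^2   # strictly inside occludes
      if (!any(accessible)) break
    }
    out[i] <- 4 * pi * rr[i]^2 * sum(accessible) / n_points
  }
  structure$sasa <- out
  attr(structure, "probe") <- probe
  attr(structure, "n_points") <- n_points
  attr(structure, "radii") <- radii
  structure
}

# deterministic Fibonacci (golden-angle) lattice on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Aggregate atom SASA to residues
#'
#' @param sasa_atoms Result of [sasa()].
#' @return Per-residue tibble: `chain`, `res_seq`, `icode`, `res_name`,
#'   `sasa` and `rel_sasa` (relative to the Gly-X-Gly theoretical maximum
#'   for the residue type; `NA` for unknown residue names).
#' @export
residue_sasa <- function(sasa_atoms) {
  stopifnot("sasa" %in% names(sasa_atoms))
  res <- sasa_atoms |>
    dplyr::group_by(.data$chain, .data$res_seq, .data$icode, .data$res_name) |>
    dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop")
  res$rel_sasa <- res$sasa / unname(MAX_SASA_GXG[res$res_name])
  res
}

#' Buried surface area and interface characterisation of a two-chain complex
#'
#' Quantifies the binding surface between two chains: the buried surface
#' area \eqn{BSA = (SASA_A + SASA_B - SASA_{AB}) / 2}, the interface
#' residue set (residues losing more than `delta_threshold` square
#' angstrom of SASA upon complexation) and the hydrophobic fraction of
#' that set under the chosen hydropathy scheme.
#'
#' @param structure Atom tibble containing both chains.
#' @param chain_a,chain_b Chain ids.
#' @param delta_threshold Minimum per-residue SASA loss (square angstrom)
#'   for interface membership (default 1.0).
#' @param scheme Hydropathy scheme id, see [hydropathy_scheme()].
#' @param ... Passed on to [sasa()] (probe, n_points, radii).
#' @return A list of class `interface_report`: `bsa`, `residues`
#'   (per-residue tibble with `sasa_isolated`, `sasa_complex`,
#'   `delta_sasa`, `interface`, `hydrophobic`), `hydrophobic_fraction`
#'   (of interface residues; `NaN` when the interface is empty) and the
#'   parameters. Symmetric in chain order.
#' @export
interface_bsa <- function(structure, chain_a, chain_b,
                          delta_threshold = 1.0, scheme = "phi", ...) {
  structure <- as_structure(structure)
  for (ch in c(chain_a, chain_b)) {
    if (!any(structure$chain == ch)) {
      abort(sprintf("chain '%s' not present in structure", ch),
            class = "calmscape_selection_error")
    }
  }
  both <- structure[structure$chain %in% c(chain_a, chain_b), ]
  s_ab <- residue_sasa(sasa(both, ...))
  s_a <- residue_sasa(sasa(both[both$chain == chain_a, ], ...))
  s_b <- residue_sasa(sasa(both[both$chain == chain_b, ], ...))
  iso <- dplyr::bind_rows(s_a, s_b)
  res <- dplyr::inner_join(
    dplyr::select(iso, "chain", "res_seq", "icode", "res_name",
                  sasa_isolated = "sasa"),
    dplyr::select(s_ab, "chain", "res_seq", "icode",
                  sasa_complex = "sasa"),
    by = c("chain", "res_seq", "icode"))
  res$delta_sasa <- res$sasa_isolated - res$sasa_complex
  res$interface <- res$delta_sasa > delta_threshold
  sch <- hydropathy_scheme(scheme)
  aa1 <- dplyr::coalesce(unname(AA_ONE[res$res_name]), "X")
  res$hydrophobic <- aa1 %in% sch$residue[sch$class == "hydrophobic"]
  bsa <- (sum(s_a$sasa) + sum(s_b$sasa) - sum(s_ab$sasa)) / 2
  structure(list(
    bsa = max(bsa, 0),
    residues = res,
    hydrophobic_fraction = mean(res$hydrophobic[res$interface]),
    chain_a = chain_a, chain_b = chain_b,
    delta_threshold = delta_threshold, scheme = scheme
  ), class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("Interface %s:%s  BSA %.1f A^2, %d interface residue(s), hydrophobic fraction %s\n",
              x$chain_a, x$chain_b, x$bsa, sum(x$residues$interface),
              ifelse(is.nan(x$hydrophobic_fraction), "-",
                     sprintf("%.2f", x$hydrophobic_fraction))))
  invisible(x)
}

#' @export
tidy.interface_report <- function(x, ...) x$residues

#' @export
glance.interface_report <- function(x, ...) {
  tibble::tibble(bsa = x$bsa, n_interface = sum(x$residues$interface),
                 hydrophobic_fraction = x$hydrophobic_fraction)
}

#' Detect exposed hydrophobic surface patches
#'
#' Surface residues (relative SASA above `exposure_cutoff`) classified
#' hydrophobic under the scheme are clustered into patches: connected
#' components of the graph linking residues whose closest inter-atomic
#' distance is at most `adjacency_cutoff`. Patches are reported largest
#' summed SASA first.
#'
#' @param structure Atom tibble.
#' @param chain Optional chain restriction.
#' @param scheme Hydropathy scheme id.
#' @param exposure_cutoff Relative-SASA threshold for surface residues
#'   (default 0.05).
#' @param adjacency_cutoff Maximum inter-atom distance (angstrom) linking
#'   two residues into one patch (default 4.5).
#' @param ... Passed on to [sasa()].
#' @return A tibble, one row per patch: `patch`, `n_residues`,
#'   `total_sasa`, `residues` (list column of residue labels).
#' @export
hydrophobic_patches <- function(structure, chain = NULL, scheme = "phi",
                                exposure_cutoff = 0.05,
                                adjacency_cutoff = 4.5, ...) {
  structure <- as_structure(structure)
  if (!is.null(chain)) structure <- structure[structure$chain %in% chain, ]
  at <- sasa(structure, ...)
  res <- residue_sasa(at)
  sch <- hydropathy_scheme(scheme)
  aa1 <- dplyr::coalesce(unname(AA_ONE[res$res_name]), "X")
  res$hydrophobic <- aa1 %in% sch$residue[sch$class == "hydrophobic"]
  keep <- res$hydrophobic & !is.na(res$rel_sasa) &
    res$rel_sasa > exposure_cutoff
  res <- res[keep, ]
  empty <- tibble::tibble(patch = integer(), n_residues = integer(),
                          total_sasa = numeric(), residues = list())
  if (nrow(res) == 0) return(empty)
  key <- paste(res$chain, res$res_seq, res$icode)
  at$key <- paste(at$chain, at$res_seq, at$icode)
  at <- at[at$key %in% key, ]
  # residue adjacency by minimum inter-atom distance
  adj <- matrix(FALSE, nrow(res), nrow(res))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ridx <- match(at$key, key)
  for (i in seq_len(nrow(res))) {
    ai <- xyz[ridx == i, , drop = FALSE]
    for (j in seq_len(nrow(res))) {
      if (j <= i) next
      aj <- xyz[ridx == j, , drop = FALSE]
      dmin2 <- min(outer(rowSums(ai^2), rowSums(aj^2), "+") -
                     2 * ai %*% t(aj))
      adj[i, j] <- adj[j, i] <- dmin2 <= adjacency_cutoff^2
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  label <- sprintf("%s%d%s", res$chain, res$res_seq, res$icode)
  out <- tibble::tibble(member = comp, label = label, sasa = res$sasa) |>
    dplyr::group_by(.data$member) |>
    dplyr::summarise(n_residues = dplyr::n(),
                     total_sasa = sum(.data$sasa),
                     residues = list(.data$label), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_sasa)) |>
    dplyr::mutate(patch = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"member")
  out
}
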