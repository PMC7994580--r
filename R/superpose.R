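#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' root-mean-square deviation between paired coordinate sets, i.e. the
#' least-squares fit of `x` onto `y` under `y ~ x R' + t`. The SVD-based
#' solution enforces `det(R) = +1` (no reflections).
#'
#' @param x,y Numeric n-by-3 coordinate matrices of corresponding points
#'   (n >= 3, non-collinear).
#' @return A `superposition` object: `rotation` (3x3), `translation`
#'   (length 3), `rmsd` (angstrom), `n_retained`, `n_input`,
#'   `cycles_run = 1`, `rejected = list()`.
#' @examples
#' pair <- simulate_structure_pair(10, angle = pi / 2,
#'                                 translation = c(1, 2, 3), seed = 1)
#' fit <- kabsch(as.matrix(pair$a[, c("x", "y", "z")]),
#'               as.matrix(pair$b[, c("x", "y", "z")]))
#' fit$rmsd   # ~0
#' @export
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != 3 || ncol(y) != 3 || nrow(x) != nrow(y)) {
    stop_input("`x` and `y` must be n-by-3 matrices of equal size")
  }
  if (nrow(x) < 3) {
    abort("superposition needs at least 3 point pairs",
          class = "calmscape_superposition_error")
  }
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  if (svd(x0)$d[2] < 1e-8 * max(1, svd(x0)$d[1])) {
    abort("degenerate (collinear) geometry; superposition is ill-defined",
          class = "calmscape_superposition_error")
  }
  H <- t(x0) %*% y0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- as.vector(cy - R %*% cx)
  fitted <- x %*% t(R) + matrix(t_vec, nrow(x), 3, byrow = TRUE)
  dev <- sqrt(rowSums((fitted - y)^2))
  new_superposition(rotation = R, translation = t_vec,
                    rmsd = sqrt(mean(dev^2)), deviations = dev,
                    n_retained = nrow(x), n_input = nrow(x),
                    cycles_run = 1L, rejected = list(),
                    retained = seq_len(nrow(x)))
}

new_superposition <- function(...) {
  structure(list(...), class = "superposition")
}

#' Apply a superposition transform to coordinates or a structure
#'
#' @param x An n-by-3 coordinate matrix or an atom tibble.
#' @param fit A `superposition` object.
#' @return The transformed coordinates/structure.
#' @export
apply_transform <- function(x, fit) {
  stopifnot(inherits(fit, "superposition"))
  if (is.data.frame(x)) {
    xyz <- as.matrix(x[, c("x", "y", "z")])
    xyz <- xyz %*% t(fit$rotation) +
      matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)
    x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
    x
  } else {
    as.matrix(x) %*% t(fit$rotation) +
      matrix(fit$translation, nrow(x), 3, byrow = TRUE)
  }
}

# iterative fit with outlier rejection on coordinate matrices;
# groups (optional) rejects whole groups by their RMS deviation
iterative_fit <- function(x, y, groups = NULL, max_cycles = 5,
                          reject_factor = 2) {
  n <- nrow(x)
  retained <- seq_len(n)
  rejected_hist <- list()
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    fit <- kabsch(x[retained, , drop = FALSE], y[retained, , drop = FALSE])
    fitted <- apply_transform(x, fit)
    dev <- sqrt(rowSums((fitted - y)^2))
    if (cycles >= max_cycles || !is.finite(reject_factor)) break
    cutoff <- reject_factor * fit$rmsd
    if (is.null(groups)) {
      cand <- retained[dev[retained] > cutoff]
    } else {
      g <- groups[retained]
      grms <- tapply(dev[retained]^2, g, function(v) sqrt(mean(v)))
      bad_groups <- names(grms)[grms > cutoff]
      cand <- retained[g %in% bad_groups]
    }
    if (length(cand) == 0 || length(retained) - length(cand) < 3) break
    rejected_hist[[cycles]] <- cand
    retained <- setdiff(retained, cand)
  }
  new_superposition(rotation = fit$rotation, translation = fit$translation,
                    rmsd = fit$rmsd, deviations = dev,
                    n_retained = length(retained), n_input = n,
                    cycles_run = cycles, rejected = rejected_hist,
                    retained = retained)
}

#' Superpose a mobile structure onto a target with outlier rejection
#'
#' Rigid-body superposition in the style of refinement-with-rejection
#' structural alignment: atoms are paired by chain, residue number,
#' insertion code and atom name under the chosen `selection`; the pair
#' set is fitted by [kabsch()]; and pairs deviating by more than
#' `reject_factor` times the current RMSD are discarded, cyclically,
#' until no rejection occurs, fewer than 3 pairs would remain, or
#' `max_cycles` fits have been run. The final RMSD is reported over the
#' retained atoms only.
#'
#' Rejection granularity defaults to whole residues (a residue is
#' rejected when the RMS deviation of its selected atoms exceeds the
#' cutoff), which keeps genuinely displaced residues and coordinate
#' noise apart; `reject_by = "atom"` rejects individual atom pairs.
#'
#' `mobile` and `target` may also be plain n-by-3 coordinate matrices in
#' pre-established correspondence (row i pairs with row i).
#'
#' @param mobile,target Atom tibbles (or coordinate matrices).
#' @param selection Atom selection: `"backbone"` (N, CA, C, O; default),
#'   `"CA"`, or `"all"`.
#' @param max_cycles Maximum fit cycles (default 5).
#' @param reject_factor Rejection cutoff as a multiple of the current
#'   RMSD (default 2.0); `Inf` disables rejection.
#' @param reject_by `"residue"` (default) or `"atom"`.
#' @return A `superposition` object; for structure input, `pairs` holds
#'   the atom-pair bookkeeping (chain, residue, atom, final deviation,
#'   retained flag).
#' @examples
#' pair <- simulate_structure_pair(20, angle = 1, noise_sd = 0.1,
#'                                 n_outliers = 2,
#'                                 outlier_displacement = 10, seed = 7)
#' fit <- superpose(pair$a, pair$b)
#' glance(fit)
#' @export
superpose <- function(mobile, target, selection = c("backbone", "CA", "all"),
                      max_cycles = 5, reject_factor = 2,
                      reject_by = c("residue", "atom")) {
  selection <- match.arg(selection)
  reject_by <- match.arg(reject_by)
  if (!is.data.frame(mobile)) {
    fit <- iterative_fit(as.matrix(mobile), as.matrix(target),
                         groups = NULL, max_cycles = max_cycles,
                         reject_factor = reject_factor)
    fit$selection <- "coordinates"
    return(fit)
  }
  mobile <- as_structure(mobile); target <- as_structure(target)
  keep <- switch(selection,
                 backbone = c("N", "CA", "C", "O"),
                 CA = "CA", all = NULL)
  sel <- function(s) {
    if (is.null(keep)) s else s[trimws(s$atom_name) %in% keep, ]
  }
  m <- sel(mobile); t_ <- sel(target)
  pairs <- dplyr::inner_join(
    dplyr::select(m, "chain", "res_seq", "icode", "atom_name",
                  mx = "x", my = "y", mz = "z"),
    dplyr::select(t_, "chain", "res_seq", "icode", "atom_name",
                  tx = "x", ty = "y", tz = "z"),
    by = c("chain", "res_seq", "icode", "atom_name"))
  if (nrow(pairs) < 3) {
    abort("fewer than 3 corresponding atoms under the chosen selection",
          class = "calmscape_superposition_error")
  }
  groups <- if (reject_by == "residue") {
    paste(pairs$chain, pairs$res_seq, pairs$icode)
  }
  fit <- iterative_fit(as.matrix(pairs[, c("mx", "my", "mz")]),
                       as.matrix(pairs[, c("tx", "ty", "tz")]),
                       groups = groups, max_cycles = max_cycles,
                       reject_factor = reject_factor)
  fit$selection <- selection
  fit$pairs <- tibble::tibble(
    chain = pairs$chain, res_seq = pairs$res_seq, icode = pairs$icode,
    atom_name = pairs$atom_name, deviation = fit$deviations,
    retained = seq_len(nrow(pairs)) %in% fit$retained)
  fit$rejected_residues <- sort(unique(
    fit$pairs$res_seq[!fit$pairs$retained]))
  fit
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: RMSD %.3f A over %d of %d atom pairs (%d cycle%s)\n",
              x$rmsd, x$n_retained, x$n_input, x$cycles_run,
              if (x$cycles_run == 1) "" else "s"))
  if (!is.null(x$selection)) cat(sprintf("  selection: %s\n", x$selection))
  if (length(x$rejected) > 0) {
    cat(sprintf("  rejected %d pair(s) over %d rejection cycle(s)\n",
                x$n_input - x$n_retained, length(x$rejected)))
  }
  invisible(x)
}

#' @export
tidy.superposition <- function(x, ...) {
  if (!is.null(x$pairs)) return(x$pairs)
  tibble::tibble(pair = seq_len(x$n_input), deviation = x$deviations,
                 retained = seq_len(x$n_input) %in% x$retained)
}

#' @export
glance.superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_retained = x$n_retained,
                 n_input = x$n_input, cycles_run = x$cycles_run,
                 selection = x$selection %||% "coordinates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structure-based sequence alignment from a superposition
#'
#' After applying the fitted transform, pairs residues of the two chains
#' greedily by C-alpha distance (closest first, each residue used once,
#' pairs beyond `pair_cutoff` discarded, and crossings forbidden so
#' sequence order is preserved; ties broken towards the lower mobile
#' residue number). The paired residues are then laid out as a two-row
#' gapped sequence alignment.
#'
#' @param mobile,target Atom tibbles used for the fit.
#' @param fit `superposition` from [superpose()].
#' @param chain_mobile,chain_target Chain ids (default: first chain of
#'   each structure).
#' @param pair_cutoff Maximum C-alpha distance (angstrom) for a residue
#'   pair; default 4.0.
#' @return A list of class `structure_alignment`: `pairs` (tibble
#'   `res_mobile`, `res_target`, `distance`) and `alignment` (named
#'   character vector of two gapped one-letter sequences). Empty (with a
#'   warning) when no residue pair falls under the cutoff.
#' @export
structure_alignment <- function(mobile, target, fit,
                                chain_mobile = NULL, chain_target = NULL,
                                pair_cutoff = 4) {
  mobile <- as_structure(mobile); target <- as_structure(target)
  chain_mobile <- chain_mobile %||% mobile$chain[1]
  chain_target <- chain_target %||% target$chain[1]
  m_ca <- mobile[trimws(mobile$atom_name) == "CA" &
                   mobile$chain == chain_mobile, ]
  t_ca <- target[trimws(target$atom_name) == "CA" &
                   target$chain == chain_target, ]
  m_ca <- apply_transform(m_ca, fit)
  m_seq <- structure_sequence(m_ca, chain_mobile)
  t_seq <- structure_sequence(t_ca, chain_target)
  mx <- as.matrix(m_ca[, c("x", "y", "z")])
  tx <- as.matrix(t_ca[, c("x", "y", "z")])
  d2 <- outer(rowSums(mx^2), rowSums(tx^2), "+") - 2 * mx %*% t(tx)
  d <- sqrt(pmax(d2, 0))
  cand <- which(d <= pair_cutoff, arr.ind = TRUE)
  out_pairs <- tibble::tibble(res_mobile = integer(), res_target = integer(),
                              distance = numeric())
  if (nrow(cand) > 0) {
    ord <- order(d[cand], cand[, 1])
    cand <- cand[ord, , drop = FALSE]
    used_m <- logical(nrow(mx)); used_t <- logical(nrow(tx))
    acc <- matrix(integer(), ncol = 2)
    dist_acc <- numeric()
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_m[i] || used_t[j]) next
      if (nrow(acc) > 0 &&
          any((i - acc[, 1]) * (j - acc[, 2]) <= 0)) next
      acc <- rbind(acc, c(i, j))
      dist_acc <- c(dist_acc, d[i, j])
      used_m[i] <- TRUE; used_t[j] <- TRUE
    }
    if (nrow(acc) > 0) {
      ord2 <- order(acc[, 1])
      out_pairs <- tibble::tibble(
        res_mobile = m_ca$res_seq[acc[ord2, 1]],
        res_target = t_ca$res_seq[acc[ord2, 2]],
        distance = dist_acc[ord2],
        idx_mobile = acc[ord2, 1], idx_target = acc[ord2, 2])
    }
  }
  if (nrow(out_pairs) == 0) {
    warn("no residue pairs under the distance cutoff; alignment is empty")
    aln <- stats::setNames(c("", ""), c(chain_mobile, chain_target))
  } else {
    row_m <- character(); row_t <- character()
    pi <- 1L; pj <- 1L
    for (k in seq_len(nrow(out_pairs))) {
      i <- out_pairs$idx_mobile[k]; j <- out_pairs$idx_target[k]
      while (pi < i) { row_m <- c(row_m, m_seq$aa[pi]); row_t <- c(row_t, "-"); pi <- pi + 1L }
      while (pj < j) { row_m <- c(row_m, "-"); row_t <- c(row_t, t_seq$aa[pj]); pj <- pj + 1L }
      row_m <- c(row_m, m_seq$aa[i]); row_t <- c(row_t, t_seq$aa[j])
      pi <- pi + 1L; pj <- pj + 1L
    }
    while (pi <= nrow(m_seq)) { row_m <- c(row_m, m_seq$aa[pi]); row_t <- c(row_t, "-"); pi <- pi + 1L }
    while (pj <= nrow(t_seq)) { row_m <- c(row_m, "-"); row_t <- c(row_t, t_seq$aa[pj]); pj <- pj + 1L }
    aln <- stats::setNames(c(paste0(row_m, collapse = ""),
                             paste0(row_t, collapse = "")),
                           c(chain_mobile, chain_target))
  }
  structure(list(pairs = dplyr::select(out_pairs, "res_mobile",
                                       "res_target", "distance"),
                 alignment = aln, pair_cutoff = pair_cutoff),
            class = "structure_alignment")
}

#' @export
print.structure_alignment <- function(x, ...) {
  cat(sprintf("Structure-based alignment: %d residue pairs (cutoff %.1f A)\n",
              nrow(x$pairs), x$pair_cutoff))
  for (nm in names(x$alignment)) cat(sprintf("  %s: %s\n", nm, x$alignment[nm]))
  invisible(x)
}

#' @export
tidy.structure_alignment <- function(x, ...) x$pairs
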