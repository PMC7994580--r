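#' Shannon entropy of one alignment column
#'
#' Computes the per-site Shannon entropy in bits,
#' \deqn{H = -\sum_i \frac{n_i}{N} \log_2 \frac{n_i}{N},}
#' where the sum runs over the 20 standard amino acids, \eqn{n_i} is the
#' number of sequences carrying amino acid \eqn{i} at the site and \eqn{N}
#' is the total count. \eqn{H = 0} means the site is completely conserved;
#' the maximum, \eqn{\log_2 20 \approx 4.32} bits, means every amino acid
#' is equally likely.
#'
#' By default \eqn{N} is the number of amino-acid residues actually
#' observed in the column (`N_total = NULL`), so gaps and nonstandard
#' residues are excluded from both numerator and denominator and the
#' probabilities normalise. Passing an explicit `N_total` (e.g. the number
#' of alignment rows) reproduces the literal-denominator variant.
#'
#' @param counts Named numeric vector of amino-acid counts. Names must be
#'   one-letter codes from [AA_ALPHABET]; missing residues count 0.
#' @param N_total Optional denominator overriding `sum(counts)`.
#' @param base Logarithm base, `"log2"` (bits, default) or `"ln"` (nats).
#' @return Entropy as a single number, or `NA_real_` for an empty column
#'   (no standard residues observed).
#' @examples
#' column_entropy(c(A = 83))                    # fully conserved -> 0
#' column_entropy(setNames(rep(5, 20), AA_ALPHABET))  # uniform -> log2(20)
#' @export
column_entropy <- function(counts, N_total = NULL, base = c("log2", "ln")) {
  base <- match.arg(base)
  if (is.null(names(counts)) || !all(names(counts) %in% AA_ALPHABET)) {
    stop_input("`counts` must be named with one-letter amino-acid codes")
  }
  if (any(counts < 0)) stop_input("`counts` must be non-negative")
  n <- counts[counts > 0]
  if (length(n) == 0) return(NA_real_)
  N <- if (is.null(N_total)) sum(n) else N_total
  if (N < sum(n)) stop_input("`N_total` is smaller than the summed counts")
  p <- n / N
  h <- -sum(p * log2(p)) + 0   # `+ 0` normalises IEEE negative zero
  if (base == "ln") h <- h * log(2)
  h
}

# per-column counts for an alignment character matrix
count_columns <- function(m) {
  ncol_m <- ncol(m)
  counts <- matrix(0L, nrow = 20, ncol = ncol_m, dimnames = list(AA_ALPHABET, NULL))
  n_gap <- integer(ncol_m)
  n_nonstd <- integer(ncol_m)
  for (j in seq_len(ncol_m)) {
    col <- m[, j]
    tab <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    counts[, j] <- as.integer(tab)
    n_gap[j] <- sum(col == "-")
    n_nonstd[j] <- sum(!(col %in% AA_ALPHABET) & col != "-")
  }
  list(counts = counts, n_gap = n_gap, n_nonstandard = n_nonstd)
}

#' Per-column Shannon entropy profile of an alignment
#'
#' Computes the conservation profile of a protein multiple sequence
#' alignment: one Shannon entropy value (bits) per column, together with
#' the column bookkeeping needed for audit (residue counts, gaps,
#' nonstandard residues, majority residue) and a conserved flag at the
#' display cap. Columns containing no standard residue at all get
#' `H = NA` and `undefined = TRUE`, never a silent zero.
#'
#' @param aln A data frame with columns `id` and `seq` (equal-width
#'   aligned sequences), as returned by [read_alignment()] or
#'   [simulate_msa()].
#' @param cap Conservation cap in bits; a column is flagged `conserved`
#'   iff `H < cap` (strict). Default 0.3, which corresponds to roughly
#'   97% majority identity (see [identity_for_entropy()]).
#' @param gaps How the denominator \eqn{N} treats gaps/nonstandard
#'   residues: `"exclude"` (default; \eqn{N} = observed standard
#'   residues) or `"count"` (\eqn{N} = number of rows).
#' @param base Logarithm base passed to [column_entropy()].
#' @return A tibble (class `calm_entropy`) with one row per column:
#'   `column`, `H`, `n_eff`, `n_gap`, `n_nonstandard`, `top_residue`,
#'   `top_fraction`, `conserved`, `undefined`. The cap is stored in
#'   `attr(, "cap")`.
#' @examples
#' aln <- tibble::tibble(id = c("a", "b"), seq = c("AAC", "AGC"))
#' entropy_profile(aln)
#' @export
entropy_profile <- function(aln, cap = 0.3, gaps = c("exclude", "count"),
                            base = c("log2", "ln")) {
  gaps <- match.arg(gaps)
  base <- match.arg(base)
  m <- aln_matrix(aln)
  cc <- count_columns(m)
  n_rows <- nrow(m)
  H <- vapply(seq_len(ncol(m)), function(j) {
    cj <- cc$counts[, j]
    if (sum(cj) == 0) return(NA_real_)
    column_entropy(cj, N_total = if (gaps == "count") n_rows else NULL,
                   base = base)
  }, numeric(1))
  n_eff <- colSums(cc$counts)
  top_idx <- apply(cc$counts, 2, which.max)
  top_residue <- ifelse(n_eff > 0, AA_ALPHABET[top_idx], NA_character_)
  top_fraction <- ifelse(n_eff > 0,
                         cc$counts[cbind(top_idx, seq_len(ncol(m)))] / n_eff,
                         NA_real_)
  out <- tibble::tibble(
    column = seq_len(ncol(m)),
    H = H,
    n_eff = as.integer(n_eff),
    n_gap = cc$n_gap,
    n_nonstandard = cc$n_nonstandard,
    top_residue = top_residue,
    top_fraction = top_fraction,
    conserved = !is.na(H) & H < cap,
    undefined = is.na(H)
  )
  attr(out, "cap") <- cap
  class(out) <- c("calm_entropy", class(out))
  out
}

# entropy (bits) of the majority-p family: majority residue at p, the
# remaining mass uniform over the other 19 amino acids
entropy_for_identity <- function(p) {
  check_fraction(p, "p", lo = 1 / 20, hi = 1)
  q <- (1 - p) / 19
  h_maj <- ifelse(p > 0, -p * log2(p), 0)
  h_rest <- ifelse(q > 0, -19 * q * log2(q), 0)
  h_maj + h_rest
}

#' Majority identity fraction corresponding to a target entropy
#'
#' Inverts the per-site entropy under the "majority residue plus uniform
#' remainder" model: finds the majority fraction \eqn{p} such that a
#' column with one residue at frequency \eqn{p} and the other 19 amino
#' acids each at \eqn{(1-p)/19} has Shannon entropy `H_target` bits.
#' Used to translate the conservation cap into a percent-identity reading
#' (e.g. a cap of 0.3 bits corresponds to approximately 97% identity).
#'
#' @param H_target Target entropy in bits, in `[0, log2(20)]`. Vectorised.
#' @param tol Root-finding tolerance on `p`.
#' @return The majority fraction(s) `p` in `[0.05, 1]`.
#' @examples
#' identity_for_entropy(0.3)   # ~0.97
#' identity_for_entropy(0)     # exactly 1
#' @export
identity_for_entropy <- function(H_target, tol = 1e-10) {
  h_max <- log2(20)
  if (!is.numeric(H_target) || any(!is.finite(H_target)) ||
      any(H_target < 0) || any(H_target > h_max + 1e-12)) {
    stop_input(sprintf("`H_target` must lie in [0, %.4f] bits", h_max))
  }
  vapply(H_target, function(h) {
    if (h <= 0) return(1)
    if (h >= h_max) return(1 / 20)
    # entropy_for_identity is strictly decreasing in p on (1/20, 1]
    stats::uniroot(function(p) entropy_for_identity(p) - h,
                   lower = 1 / 20, upper = 1, tol = tol)$root
  }, numeric(1))
}

#' Plot an entropy profile
#'
#' @param object An [entropy_profile()] result.
#' @param ... Unused.
#' @return A ggplot object: per-column entropy with the conservation cap.
#' @exportS3Method ggplot2::autoplot
autoplot.calm_entropy <- function(object, ...) {
  cap <- attr(object, "cap")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$column, y = .data$H)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$conserved), size = 1) +
    ggplot2::geom_hline(yintercept = cap, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "Alignment column", y = "Shannon entropy (bits)",
                  colour = sprintf("H < %.2g", cap)) +
    ggplot2::theme_minimal()
}

#' Write an entropy profile as TSV
#'
#' @param profile Result of [entropy_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
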