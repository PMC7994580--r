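#' Build a position-specific scoring matrix from seed motif instances
#'
#' Computes per-column log-odds scores (bits) from an ungapped, aligned
#' set of motif instances:
#' \deqn{s_{c,a} = \log_2 \frac{n_{c,a} + q\,b_a}{(N + q)\, b_a},}
#' where \eqn{n_{c,a}} counts residue \eqn{a} in column \eqn{c}, \eqn{N}
#' is the number of instances, \eqn{q} the total pseudocount (distributed
#' by the background) and \eqn{b_a} the background frequency.
#'
#' @param instances Character vector (or data frame with a `seq` column)
#'   of at least 2 equal-length, gap-free sequences over the standard
#'   alphabet.
#' @param pseudocount Total pseudocount `q` (default 1).
#' @param background Length-20 background frequencies in [AA_ALPHABET]
#'   order, summing to 1; default uniform.
#' @return A `pssm` object: `log_odds` (width x 20 matrix, bits),
#'   `width`, `consensus`, `max_score`, `pseudocount`, `background`.
#' @examples
#' p <- build_pssm(c("ACDEF", "ACDEW", "ACDEF"))
#' p$consensus
#' @export
build_pssm <- function(instances, pseudocount = 1, background = NULL) {
  if (is.data.frame(instances)) instances <- instances$seq
  instances <- toupper(instances)
  if (length(instances) < 2) stop_input("need at least 2 seed instances")
  w <- unique(nchar(instances))
  if (length(w) != 1) stop_input("seed instances must have equal length")
  if (any(grepl("-", instances, fixed = TRUE))) {
    stop_input("seed instances must be ungapped")
  }
  if (pseudocount < 0) stop_input("`pseudocount` must be >= 0")
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (length(background) != 20 || abs(sum(background) - 1) > 1e-8 ||
      any(background <= 0)) {
    stop_input("`background` must be 20 positive frequencies summing to 1")
  }
  background <- stats::setNames(as.numeric(background), AA_ALPHABET)
  m <- matrix(unlist(strsplit(instances, "", fixed = TRUE)),
              nrow = length(instances), byrow = TRUE)
  if (!all(m %in% AA_ALPHABET)) {
    stop_input("seed instances must use the 20 standard amino acids")
  }
  N <- length(instances)
  counts <- t(apply(m, 2, function(col) {
    table(factor(col, levels = AA_ALPHABET))
  }))
  log_odds <- log2(sweep(counts + pseudocount * matrix(background, w, 20,
                                                       byrow = TRUE),
                         2, (N + pseudocount) * background, "/"))
  colnames(log_odds) <- AA_ALPHABET
  structure(list(
    log_odds = log_odds, width = w,
    consensus = paste0(AA_ALPHABET[apply(log_odds, 1, which.max)],
                       collapse = ""),
    max_score = sum(apply(log_odds, 1, max)),
    pseudocount = pseudocount, background = background
  ), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: width %d, consensus %s, max score %.2f bits\n",
              x$width, x$consensus, x$max_score))
  invisible(x)
}

#' @export
tidy.pssm <- function(x, ...) {
  tibble::as_tibble(x$log_odds) |>
    dplyr::mutate(position = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"position", names_to = "residue",
                        values_to = "score")
}

# window scores for one sequence; positions with nonstandard residues
# (X etc.) contribute 0 to any window covering them
window_scores <- function(pssm, seq) {
  s <- chars(toupper(seq))
  L <- length(s)
  w <- pssm$width
  if (L < w) return(numeric(0))
  idx <- match(s, AA_ALPHABET)
  idx[is.na(idx)] <- 21L
  M <- cbind(pssm$log_odds, 0)
  K <- L - w + 1
  sc <- numeric(K)
  for (j in seq_len(w)) {
    contrib <- unname(M[j, idx])
    sc <- sc + contrib[j:(j + K - 1)]
  }
  sc
}

# greedy non-overlap pruning: best score first, ties leftmost
prune_overlaps <- function(df) {
  if (nrow(df) <= 1) return(df)
  df <- df[order(-df$score, df$start), ]
  kept <- logical(0)
  acc_start <- integer(0); acc_end <- integer(0)
  take <- logical(nrow(df))
  for (k in seq_len(nrow(df))) {
    s <- df$start[k]; e <- df$end[k]
    if (all(e < acc_start | s > acc_end)) {
      take[k] <- TRUE
      acc_start <- c(acc_start, s); acc_end <- c(acc_end, e)
    }
  }
  df <- df[take, ]
  df[order(df$start), ]
}

#' Scan sequences with a PSSM
#'
#' Scores every window of each sequence against the matrix and reports
#' windows at or above `threshold`, greedily pruned to a non-overlapping
#' set (highest score first, ties towards the leftmost window).
#' Positions are 1-based inclusive.
#'
#' @param sequences Data frame with `id` and `seq` columns, or a
#'   character vector of sequences.
#' @param pssm A [build_pssm()] object.
#' @param threshold Minimum window score in bits; default 60% of the
#'   matrix's maximum achievable score. See [calibrate_thresholds()] for
#'   a null-calibrated alternative.
#' @return A tibble: `id`, `start`, `end`, `score`.
#' @export
scan_pssm <- function(sequences, pssm, threshold = NULL) {
  stopifnot(inherits(pssm, "pssm"))
  if (!is.data.frame(sequences)) {
    sequences <- tibble::tibble(
      id = names(sequences) %||% sprintf("seq%03d", seq_along(sequences)),
      seq = as.character(sequences))
  }
  threshold <- threshold %||% (0.6 * pssm$max_score)
  purrr::map2(sequences$id, sequences$seq, function(id, sq) {
    sc <- window_scores(pssm, sq)
    hit <- which(sc >= threshold)
    if (length(hit) == 0) return(NULL)
    prune_overlaps(tibble::tibble(
      id = id, start = hit, end = hit + pssm$width - 1L,
      score = sc[hit]))
  }) |> purrr::compact() |> dplyr::bind_rows() |>
    (\(d) if (nrow(d) == 0) {
      tibble::tibble(id = character(), start = integer(),
                     end = integer(), score = numeric())
    } else d)()
}

#' Three-segment split-motif model
#'
#' Bundles three segment PSSMs with the allowed spacer ranges between
#' consecutive segments, describing a split motif: ordered segments
#' separated by variable-length spacers.
#'
#' @param segments List of exactly three `pssm` objects.
#' @param spacer_ranges List of two `(min, max)` integer pairs.
#' @return A `split_motif_model` object.
#' @export
split_motif_model <- function(segments, spacer_ranges) {
  if (length(segments) != 3 ||
      !all(vapply(segments, inherits, logical(1), "pssm"))) {
    stop_input("`segments` must be a list of exactly three pssm objects")
  }
  if (length(spacer_ranges) != 2 ||
      any(vapply(spacer_ranges, function(r) {
        length(r) != 2 || any(r < 0) || r[1] > r[2]
      }, logical(1)))) {
    stop_input("`spacer_ranges` must be two (min, max) pairs with min <= max")
  }
  structure(list(segments = segments, spacer_ranges = spacer_ranges),
            class = "split_motif_model")
}

#' @export
print.split_motif_model <- function(x, ...) {
  cat(sprintf("Split motif: widths %s; spacers [%d,%d] and [%d,%d]\n",
              paste(vapply(x$segments, `[[`, numeric(1), "width"),
                    collapse = "/"),
              x$spacer_ranges[[1]][1], x$spacer_ranges[[1]][2],
              x$spacer_ranges[[2]][1], x$spacer_ranges[[2]][2]))
  invisible(x)
}

#' Scan sequences for a three-segment split motif
#'
#' Finds candidate windows per segment (score at or above the per-segment
#' threshold), assembles them left to right into triples whose two
#' spacers fall within the model's ranges, scores triples as the sum of
#' segment scores (spacers contribute nothing), and reports a greedy
#' non-overlapping set, best total score first with ties towards the
#' leftmost placement.
#'
#' @param sequences Data frame with `id`, `seq`, or a character vector.
#' @param model A [split_motif_model()].
#' @param thresholds Length-3 numeric vector of per-segment score
#'   thresholds (bits); default 60% of each segment's maximum score.
#' @return A tibble: `id`, `start`, `end`, `seg1_start`, `seg2_start`,
#'   `seg3_start`, `spacer1`, `spacer2`, `score1`, `score2`, `score3`,
#'   `score`.
#' @examples
#' sim <- simulate_split_motifs(2, 2, 300, conservation = 1, seed = 2)
#' segs <- lapply(seq_len(3), function(k) {
#'   inst <- substr(rep(sim$consensus[k], 2), 1, nchar(sim$consensus[k]))
#'   build_pssm(inst)
#' })
#' model <- split_motif_model(segs, sim$spacer_ranges)
#' scan_split(sim$sequences, model)
#' @export
scan_split <- function(sequences, model, thresholds = NULL) {
  stopifnot(inherits(model, "split_motif_model"))
  if (!is.data.frame(sequences)) {
    sequences <- tibble::tibble(
      id = names(sequences) %||% sprintf("seq%03d", seq_along(sequences)),
      seq = as.character(sequences))
  }
  thresholds <- thresholds %||%
    vapply(model$segments, function(p) 0.6 * p$max_score, numeric(1))
  if (length(thresholds) != 3) stop_input("`thresholds` must have length 3")
  w <- vapply(model$segments, `[[`, numeric(1), "width")
  r1 <- model$spacer_ranges[[1]]; r2 <- model$spacer_ranges[[2]]
  empty <- tibble::tibble(id = character(), start = integer(),
                          end = integer(), seg1_start = integer(),
                          seg2_start = integer(), seg3_start = integer(),
                          spacer1 = integer(), spacer2 = integer(),
                          score1 = numeric(), score2 = numeric(),
                          score3 = numeric(), score = numeric())
  out <- purrr::map2(sequences$id, sequences$seq, function(id, sq) {
    cand <- lapply(seq_len(3), function(k) {
      sc <- window_scores(model$segments[[k]], sq)
      which(sc >= thresholds[k]) |>
        (\(h) tibble::tibble(start = h, score = sc[h]))()
    })
    if (any(vapply(cand, nrow, integer(1)) == 0)) return(NULL)
    # assemble triples obeying the spacer ranges
    t12 <- merge(cand[[1]], cand[[2]], by = NULL,
                 suffixes = c("1", "2")) |> tibble::as_tibble()
    t12$spacer1 <- t12$start2 - (t12$start1 + w[1])
    t12 <- t12[t12$spacer1 >= r1[1] & t12$spacer1 <= r1[2], ]
    if (nrow(t12) == 0) return(NULL)
    t123 <- merge(t12, stats::setNames(cand[[3]], c("start3", "score3")),
                  by = NULL) |> tibble::as_tibble()
    t123$spacer2 <- t123$start3 - (t123$start2 + w[2])
    t123 <- t123[t123$spacer2 >= r2[1] & t123$spacer2 <= r2[2], ]
    if (nrow(t123) == 0) return(NULL)
    t123$score <- t123$score1 + t123$score2 + t123$score3
    t123$start <- t123$start1
    t123$end <- t123$start3 + as.integer(w[3]) - 1L
    t123 <- prune_overlaps(t123)
    tibble::tibble(
      id = id, start = t123$start, end = t123$end,
      seg1_start = t123$start1, seg2_start = t123$start2,
      seg3_start = t123$start3,
      spacer1 = as.integer(t123$spacer1), spacer2 = as.integer(t123$spacer2),
      score1 = t123$score1, score2 = t123$score2, score3 = t123$score3,
      score = t123$score)
  }) |> purrr::compact() |> dplyr::bind_rows()
  if (nrow(out) == 0) empty else out
}

#' Calibrate scan thresholds on synthetic null sequences
#'
#' Scores uniform-background random sequences and returns, per segment,
#' the maximum null window score plus a safety `margin`. Scanning at the
#' calibrated threshold therefore yields (by construction) no hits on
#' background-like sequence while keeping sensitivity for genuine motif
#' instances.
#'
#' @param x A `pssm` or `split_motif_model`.
#' @param n_null Number of null sequences (default 50).
#' @param null_length Length of each null sequence (default 500).
#' @param margin Bits added to the null maximum (default 1).
#' @param seed Integer seed.
#' @return A numeric threshold (pssm) or length-3 vector (split model).
#' @export
calibrate_thresholds <- function(x, n_null = 50, null_length = 500,
                                 margin = 1, seed = 1) {
  nulls <- with_seed(seed, vapply(seq_len(n_null), function(i) {
    paste0(sample(AA_ALPHABET, null_length, replace = TRUE), collapse = "")
  }, character(1)))
  null_max <- function(p) {
    max(vapply(nulls, function(sq) max(window_scores(p, sq)), numeric(1)))
  }
  if (inherits(x, "pssm")) return(null_max(x) + margin)
  if (inherits(x, "split_motif_model")) {
    return(vapply(x$segments, null_max, numeric(1)) + margin)
  }
  stop_input("`x` must be a pssm or split_motif_model")
}

#' Summarise repeat architecture of motif hits on one sequence
#'
#' Orders the hits of a single protein and reports its domain
#' organisation as a compact string (e.g. `"CALM x3"`) with 1-based
#' inclusive start/end residue numbers per copy.
#'
#' @param hits Hit tibble (from [scan_pssm()] or [scan_split()]) for one
#'   sequence id.
#' @param seq_length Sequence length (for bounds checking).
#' @param name Domain name used in the summary (default `"CALM"`).
#' @return A tibble `domain`, `copy`, `start`, `end`, with attribute
#'   `architecture` holding the summary string (empty string for no
#'   hits).
#' @export
repeat_architecture <- function(hits, seq_length, name = "CALM") {
  if (nrow(hits) == 0) {
    out <- tibble::tibble(domain = character(), copy = integer(),
                          start = integer(), end = integer())
    attr(out, "architecture") <- ""
    return(out)
  }
  if (length(unique(hits$id)) > 1) {
    stop_input("`hits` must come from a single sequence")
  }
  hits <- hits[order(hits$start), ]
  if (any(hits$end > seq_length) || any(hits$start < 1)) {
    stop_input("hit spans exceed the sequence length")
  }
  if (nrow(hits) > 1 &&
      any(hits$start[-1] <= hits$end[-nrow(hits)])) {
    abort("overlapping hits; scan output should be non-overlapping",
          class = "calmscape_internal_error")
  }
  out <- tibble::tibble(domain = name, copy = seq_len(nrow(hits)),
                        start = as.integer(hits$start),
                        end = as.integer(hits$end))
  attr(out, "architecture") <- sprintf("%s x%d", name, nrow(out))
  attr(out, "seq_length") <- seq_length
  out
}

#' Plot motif hits along sequences
#'
#' @param hits Hit tibble from [scan_pssm()] or [scan_split()].
#' @param seq_lengths Optional named vector of sequence lengths.
#' @return A ggplot object.
#' @export
plot_architecture <- function(hits, seq_lengths = NULL) {
  p <- ggplot2::ggplot(hits)
  if (!is.null(seq_lengths)) {
    back <- tibble::tibble(id = names(seq_lengths), len = seq_lengths)
    p <- p + ggplot2::geom_segment(
      data = back,
      ggplot2::aes(x = 1, xend = .data$len, y = .data$id, yend = .data$id),
      colour = "grey80", linewidth = 1)
  }
  p + ggplot2::geom_segment(
    ggplot2::aes(x = .data$start, xend = .data$end,
                 y = .data$id, yend = .data$id, colour = .data$score),
    linewidth = 4) +
    ggplot2::labs(x = "Residue", y = NULL, colour = "Score (bits)") +
    ggplot2::theme_minimal()
}
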