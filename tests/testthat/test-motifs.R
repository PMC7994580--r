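test_that("PSSM log-odds match hand-computed values", {
  # 2 identical single-column instances, q = 1, uniform background:
  # score(A) = log2((2 + 0.05) / (3 * 0.05)) = log2(41/3)
  p <- build_pssm(c("A", "A"), pseudocount = 1)
  expect_equal(unname(p$log_odds[1, "A"]), log2(41 / 3), tolerance = 1e-12)
  expect_equal(unname(p$log_odds[1, "A"]), 3.772589, tolerance = 1e-6)
  # off-consensus cells are negative
  expect_true(all(p$log_odds[1, -1] < 0))

  # identical instances: consensus cells are log2(20 (N + q/20) / (N + q))
  p2 <- build_pssm(c("ACD", "ACD", "ACD"), pseudocount = 1)
  expected <- log2(20 * (3 + 1 / 20) / (3 + 1))
  cons <- cbind(1:3, match(c("A", "C", "D"), colnames(p2$log_odds)))
  expect_equal(unname(p2$log_odds[cons]), rep(expected, 3))
  expect_equal(p2$consensus, "ACD")
  expect_equal(p2$max_score, 3 * expected)

  # background equal to the observed composition zeroes the scores
  p3 <- build_pssm(c("AR", "RA"), pseudocount = 1,
                   background = c(0.5 - 18 * 1e-4 / 2, 0.5 - 18 * 1e-4 / 2,
                                  rep(1e-4, 18)))
  obs_cells <- cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_true(all(abs(p3$log_odds[obs_cells]) < 0.01))
})

test_that("PSSM construction validates its input", {
  expect_error(build_pssm("ACDEF"), class = "calmscape_input_error")
  expect_error(build_pssm(c("AC", "ACD")), class = "calmscape_input_error")
  expect_error(build_pssm(c("A-C", "A-C")), class = "calmscape_input_error")
  expect_error(build_pssm(c("AXC", "AYC")), class = "calmscape_input_error")
  expect_error(build_pssm(c("AC", "AC"), background = rep(1, 20)),
               class = "calmscape_input_error")
})

test_that("scanning finds exact consensus planted in background", {
  p <- build_pssm(c("WYFWC", "WYFWC", "WYFWC"))
  seqv <- paste0(strrep("G", 30), "WYFWC", strrep("G", 25))
  hits <- scan_pssm(seqv, p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 31)
  expect_equal(hits$score, p$max_score, tolerance = 1e-9)

  # threshold above the maximum yields nothing
  expect_equal(nrow(scan_pssm(seqv, p, threshold = p$max_score + 1)), 0)
  # sequences shorter than the matrix yield nothing
  expect_equal(nrow(scan_pssm("WYF", p)), 0)
  # X positions contribute zero score
  with_x <- paste0(strrep("G", 10), "WYXWC", strrep("G", 10))
  sc_full <- scan_pssm(with_x, p, threshold = -Inf)
  at11 <- sc_full$score[sc_full$start == 11]
  expect_equal(at11, p$max_score - unname(p$log_odds[3, "F"]), tolerance = 1e-9)
})

test_that("hit offsets are shift-equivariant and counts threshold-monotone", {
  sim <- simulate_split_motifs(1, 4, 120, conservation = 1, seed = 21)
  p <- build_pssm(planted_instances(sim, 2))
  base_hits <- scan_pssm(sim$sequences, p)
  shifted <- dplyr::mutate(sim$sequences,
                           seq = paste0(strrep("G", 7), .data$seq))
  shift_hits <- scan_pssm(shifted, p)
  expect_equal(shift_hits$start, base_hits$start + 7)
  expect_equal(shift_hits$score, base_hits$score)

  thr <- sort(stats::runif(5, 0, p$max_score))
  counts <- vapply(thr, function(t) nrow(scan_pssm(sim$sequences, p, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("split-motif scanning recovers planted triples with exact spacers", {
  sim <- simulate_split_motifs(2, 4, 250, conservation = 1,
                               spacer_ranges = list(c(3, 3), c(7, 7)),
                               seed = 31)
  model <- model_from_sim(sim)
  hits <- scan_split(sim$sequences, model)
  expect_equal(nrow(hits), nrow(sim$truth))
  joined <- dplyr::inner_join(
    hits, sim$truth,
    by = c("id", "seg1_start", "seg2_start", "seg3_start"))
  expect_equal(nrow(joined), nrow(sim$truth))
  expect_true(all(hits$spacer1 == 3))
  expect_true(all(hits$spacer2 == 7))
  # triple score is the sum of the segment scores
  expect_equal(hits$score, hits$score1 + hits$score2 + hits$score3)

  # the maximum copy load is recovered per sequence
  sim5 <- simulate_split_motifs(5, 3, 400, conservation = 1, seed = 32)
  hits5 <- scan_split(sim5$sequences, model_from_sim(sim5))
  expect_equal(as.integer(table(hits5$id)), rep(5L, 3))
})

test_that("spacers outside the model range gate out assembled triples", {
  sim <- simulate_split_motifs(1, 3, 150, conservation = 1,
                               spacer_ranges = list(c(6, 8), c(6, 8)),
                               seed = 41)
  segs <- lapply(1:3, function(k) build_pssm(planted_instances(sim, k)))
  narrow <- split_motif_model(segs, list(c(1, 2), c(1, 2)))
  # segment hits exist in isolation ...
  expect_gt(nrow(scan_pssm(sim$sequences, segs[[1]])), 0)
  expect_gt(nrow(scan_pssm(sim$sequences, segs[[2]])), 0)
  # ... but no triple satisfies the (too narrow) spacer ranges
  expect_equal(nrow(scan_split(sim$sequences, narrow)), 0)
})

test_that("recovery rate is non-decreasing in motif conservation", {
  rate <- vapply(c(0.7, 0.85, 1.0), function(cons) {
    sim <- simulate_split_motifs(3, 6, 400, conservation = cons, seed = 51)
    model <- model_from_sim(sim)
    thr <- calibrate_thresholds(model, n_null = 20, null_length = 400,
                                seed = 52)
    hits <- scan_split(sim$sequences, model, thresholds = thr)
    ok <- dplyr::inner_join(hits, sim$truth,
                            by = c("id", "seg1_start", "seg2_start",
                                   "seg3_start"))
    nrow(ok) / nrow(sim$truth)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_equal(rate[3], 1)
})

test_that("repeat architecture summarises ordered, bounded domains", {
  hits <- tibble::tibble(id = "p1", start = c(120, 10, 250),
                         end = c(160, 55, 300), score = c(30, 35, 28))
  arch <- repeat_architecture(hits, seq_length = 400)
  expect_equal(arch$start, c(10, 120, 250))   # sorted by offset
  expect_equal(arch$copy, 1:3)
  expect_equal(attr(arch, "architecture"), "CALM x3")

  empty <- repeat_architecture(hits[0, ], seq_length = 400)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "architecture"), "")

  overlapping <- tibble::tibble(id = "p1", start = c(10, 30),
                                end = c(40, 60), score = c(1, 2))
  expect_error(repeat_architecture(overlapping, 100),
               class = "calmscape_internal_error")
  expect_error(repeat_architecture(hits, seq_length = 200),
               class = "calmscape_input_error")
})

test_that("a single-segment GP-rich style matrix scans as an ordinary PSSM", {
  # 37-column glycine/proline-rich seed
  withr::with_seed(61, {
    gp <- vapply(1:6, function(i) {
      paste0(sample(c("G", "P", "A", "S"), 37, TRUE,
                    prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
    }, character(1))
  })
  p <- build_pssm(gp)
  expect_equal(p$width, 37)
  target <- paste0(strrep("K", 20), p$consensus, strrep("K", 20))
  hits <- scan_pssm(target, p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 21)
})
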