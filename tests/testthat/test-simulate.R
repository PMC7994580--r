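test_that("generators are reproducible under a fixed seed", {
  expect_identical(simulate_msa(10, 8, 0.9, seed = 3),
                   simulate_msa(10, 8, 0.9, seed = 3))
  expect_identical(simulate_structure_pair(8, angle = 1, seed = 3),
                   simulate_structure_pair(8, angle = 1, seed = 3))
  expect_identical(simulate_split_motifs(2, 2, 200, 0.9, seed = 3),
                   simulate_split_motifs(2, 2, 200, 0.9, seed = 3))
  expect_identical(simulate_complex(c(9, 9), 4, 0.5, seed = 3),
                   simulate_complex(c(9, 9), 4, 0.5, seed = 3))
  expect_false(identical(simulate_msa(10, 8, 0.9, seed = 3)$alignment,
                         simulate_msa(10, 8, 0.9, seed = 4)$alignment))
  # generator calls do not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(simulate_msa(5, 5, 0.9, seed = 1))
  expect_identical(stats::runif(1), before)
})

test_that("simulated alignments realise the requested column statistics", {
  # fully conserved columns
  sim1 <- simulate_msa(12, 6, column_identity = 1, seed = 1)
  expect_true(all(entropy_profile(sim1$alignment)$H == 0))
  expect_equal(entropy_profile(sim1$alignment)$top_residue,
               sim1$truth$majority)

  # 97% identity emulation at the realistic alignment depth
  sim2 <- simulate_msa(83, 120, column_identity = 0.97, seed = 2)
  prof2 <- entropy_profile(sim2$alignment)
  expect_equal(mean(prof2$top_fraction), 0.97, tolerance = 0.01)

  # near-uniform columns approach the analytic maximum at depth 2000
  sim3 <- simulate_msa(2000, 40, column_identity = 1 / 20, seed = 3)
  expect_equal(mean(entropy_profile(sim3$alignment)$H), log2(20),
               tolerance = 0.05)

  # gap plumbing
  sim4 <- simulate_msa(50, 30, 0.9, gap_rate = 0.2, seed = 4)
  expect_gt(sum(entropy_profile(sim4$alignment)$n_gap), 0)
})

test_that("msa generator rejects invalid specifications", {
  expect_error(simulate_msa(10, 5, 0.01, seed = 1),
               class = "calmscape_spec_error")
  expect_error(simulate_msa(10, 5, c(0.9, 0.9), seed = 1),
               class = "calmscape_spec_error")
  expect_error(simulate_msa(10, 5, 0.9, gap_rate = 1, seed = 1),
               class = "calmscape_spec_error")
  expect_error(simulate_msa(0, 5, 0.9, seed = 1),
               class = "calmscape_spec_error")
})

test_that("structure pairs realise the planted rigid transform exactly", {
  pair <- simulate_structure_pair(15, axis = c(1, 2, 3), angle = 0.7,
                                  translation = c(4, -1, 2), seed = 5)
  a_xyz <- as.matrix(pair$a[, c("x", "y", "z")])
  b_xyz <- as.matrix(pair$b[, c("x", "y", "z")])
  expected <- a_xyz %*% t(pair$truth$rotation) +
    matrix(pair$truth$translation, nrow(a_xyz), 3, byrow = TRUE)
  expect_equal(unname(b_xyz), unname(expected), tolerance = 1e-12)
  # backbone atom names present for atom-selection logic
  expect_setequal(unique(pair$a$atom_name), c("N", "CA", "C", "O"))
  # consecutive CA spacing is the idealised 3.8 A
  ca <- pair$a[pair$a$atom_name == "CA", c("x", "y", "z")]
  steps <- sqrt(rowSums((as.matrix(ca[-1, ]) - as.matrix(ca[-nrow(ca), ]))^2))
  expect_equal(steps, rep(3.8, nrow(ca) - 1), tolerance = 1e-9)

  # identity transform, no noise: A equals B
  ident <- simulate_structure_pair(8, angle = 0, seed = 6)
  expect_identical(ident$a[, c("x", "y", "z")], ident$b[, c("x", "y", "z")])
})

test_that("structure pair generator validates its specification", {
  expect_error(simulate_structure_pair(10, axis = c(0, 0, 0), angle = 1),
               class = "calmscape_spec_error")
  expect_error(simulate_structure_pair(10, n_outliers = 10),
               class = "calmscape_spec_error")
  expect_error(simulate_structure_pair(10, noise_sd = -1),
               class = "calmscape_spec_error")
})

test_that("split-motif sets plant instances exactly as recorded", {
  # no copies, no truth
  sim0 <- simulate_split_motifs(0, 3, 100, 0.9, seed = 1)
  expect_equal(nrow(sim0$truth), 0)
  expect_equal(nchar(sim0$sequences$seq), rep(100, 3))

  # perfect conservation: planted substrings equal the consensus
  sim1 <- simulate_split_motifs(3, 4, 400, conservation = 1, seed = 2)
  for (k in 1:3) {
    expect_true(all(planted_instances(sim1, k) == sim1$consensus[k]))
  }
  expect_true(all(sim1$truth$spacer1 >= 3 & sim1$truth$spacer1 <= 8))
  expect_true(all(sim1$truth$spacer2 >= 4 & sim1$truth$spacer2 <= 9))

  # degenerate spacer ranges pin the spacers
  sim2 <- simulate_split_motifs(2, 3, 200, 0.95,
                                spacer_ranges = list(c(3, 3), c(7, 7)),
                                seed = 3)
  expect_true(all(sim2$truth$spacer1 == 3))
  expect_true(all(sim2$truth$spacer2 == 7))

  # span overflow is a specification error
  expect_error(simulate_split_motifs(5, 2, 100, 0.9, seed = 1),
               class = "calmscape_spec_error")
  expect_error(simulate_split_motifs(6, 2, 1000, 0.9, seed = 1),
               class = "calmscape_spec_error")
})

test_that("synthetic complexes separate and classify residues as planted", {
  far <- simulate_complex(c(16, 16), interface_spacing = 100, seed = 1)
  a_xyz <- as.matrix(far$structure[far$structure$chain == "A", c("x", "y", "z")])
  b_xyz <- as.matrix(far$structure[far$structure$chain == "B", c("x", "y", "z")])
  expect_gt(min(outer(rowSums(a_xyz^2), rowSums(b_xyz^2), "+") -
                  2 * a_xyz %*% t(b_xyz)), 90^2)

  hydro <- simulate_complex(c(16, 16), 4,
                            hydrophobic_fraction_at_interface = 1, seed = 2)
  expect_true(all(hydro$truth$hydrophobic))
  sch <- hydropathy_scheme("phi")
  phi_three <- unname(calmscape:::AA_THREE[sch$residue[sch$class == "hydrophobic"]])
  expect_true(all(hydro$structure$res_name %in% phi_three))

  expect_error(simulate_complex(c(10, 10), 0, 0.5),
               class = "calmscape_spec_error")
})
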