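coords <- function(s) as.matrix(s[, c("x", "y", "z")])

test_that("Kabsch recovers exact rigid transforms", {
  pair <- simulate_structure_pair(12, axis = c(0, 0, 1), angle = pi / 2,
                                  translation = c(1, 2, 3), seed = 1)
  fit <- kabsch(coords(pair$a), coords(pair$b))
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$rotation, pair$truth$rotation, tolerance = 1e-8)
  expect_equal(fit$translation, pair$truth$translation, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-6)

  # identical coordinates: identity rotation, zero rmsd
  self_fit <- kabsch(coords(pair$a), coords(pair$a))
  expect_equal(self_fit$rotation, diag(3), tolerance = 1e-8)
  expect_equal(self_fit$rmsd, 0, tolerance = 1e-10)
})

test_that("Kabsch rejects degenerate input", {
  expect_error(kabsch(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               class = "calmscape_superposition_error")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch(line, line),
               class = "calmscape_superposition_error")
})

test_that("Kabsch RMSD matches the quaternion-method oracle", {
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(4:50, 1)
      x <- matrix(stats::rnorm(n * 3, sd = 5), ncol = 3)
      y <- matrix(stats::rnorm(n * 3, sd = 5), ncol = 3)
      expect_equal(kabsch(x, y)$rmsd, quaternion_rmsd(x, y),
                   tolerance = 1e-8)
    }
    # the spec'd small case: 4-point clouds, one point perturbed by 1 A
    x <- matrix(stats::rnorm(12), ncol = 3)
    y <- x
    y[2, ] <- y[2, ] + c(1, 0, 0)
    expect_equal(kabsch(x, y)$rmsd, quaternion_rmsd(x, y), tolerance = 1e-8)
  })
})

test_that("iterative rejection removes exactly the planted outliers", {
  pair <- simulate_structure_pair(25, axis = c(1, 1, 0), angle = 1.2,
                                  translation = c(5, 0, -3),
                                  noise_sd = 0.1, n_outliers = 2,
                                  outlier_displacement = 10, seed = 11)
  fit <- superpose(pair$a, pair$b, max_cycles = 5, reject_factor = 2)
  expect_equal(fit$rejected_residues, pair$truth$outlier_residues)
  initial <- kabsch(coords(pair$a), coords(pair$b))
  expect_lte(fit$rmsd, initial$rmsd)
  expect_equal(fit$n_retained, fit$n_input - 8)  # 2 residues x 4 atoms
  # retained residues all sit within the rejection cutoff (RMS per residue)
  kept <- fit$pairs[fit$pairs$retained, ]
  res_rms <- tapply(kept$deviation^2, kept$res_seq, function(v) sqrt(mean(v)))
  expect_true(all(res_rms <= 2 * fit$rmsd + 1e-9))
})

test_that("clean pairs and infinite reject factor reduce to a single Kabsch fit", {
  pair <- simulate_structure_pair(10, angle = 0.9, translation = c(2, 2, 2),
                                  seed = 3)
  fit <- superpose(pair$a, pair$b)
  expect_equal(fit$cycles_run, 1L)
  expect_equal(fit$n_retained, fit$n_input)

  noisy <- simulate_structure_pair(10, angle = 0.9, noise_sd = 0.5, seed = 4)
  plain <- kabsch(coords(noisy$a), coords(noisy$b))
  no_reject <- superpose(noisy$a, noisy$b, reject_factor = Inf)
  expect_equal(no_reject$rmsd, plain$rmsd, tolerance = 1e-12)
  expect_equal(no_reject$n_retained, no_reject$n_input)
})

test_that("superposition is invariant to common transforms and symmetric", {
  pair <- simulate_structure_pair(14, angle = 0.8, noise_sd = 0.2, seed = 6)
  fit_ab <- superpose(pair$a, pair$b)
  # common pre-rotation of both structures
  R <- calmscape:::rotation_from_axis_angle(c(1, 2, -1), 0.6)
  rot <- function(s) {
    xyz <- coords(s) %*% t(R) + matrix(c(7, -2, 1), nrow(s), 3, byrow = TRUE)
    s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]; s
  }
  fit_rot <- superpose(rot(pair$a), rot(pair$b))
  expect_equal(fit_rot$rmsd, fit_ab$rmsd, tolerance = 1e-9)
  expect_equal(fit_rot$n_retained, fit_ab$n_retained)

  # direction symmetry: equal rmsd, inverse transforms
  fit_ba <- superpose(pair$b, pair$a)
  expect_equal(fit_ab$rmsd, fit_ba$rmsd, tolerance = 1e-8)
  expect_equal(fit_ba$rotation %*% fit_ab$rotation, diag(3),
               tolerance = 1e-8)
})

test_that("tidy and glance expose the fit bookkeeping", {
  pair <- simulate_structure_pair(8, angle = 0.5, seed = 2)
  fit <- superpose(pair$a, pair$b)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), fit$n_input)
  gl <- glance(fit)
  expect_equal(gl$rmsd, fit$rmsd)
  expect_equal(gl$selection, "backbone")
})

test_that("structure-based alignment pairs residues in order", {
  pair <- simulate_structure_pair(12, seed = 8)
  fit <- superpose(pair$a, pair$a)
  aln <- structure_alignment(pair$a, pair$a, fit)
  expect_equal(nrow(aln$pairs), 12)          # gapless self-alignment
  expect_false(any(grepl("-", aln$alignment, fixed = TRUE)))
  expect_equal(aln$pairs$res_mobile, aln$pairs$res_target)

  # 3 N-terminal residues deleted: exactly 3 leading gaps on the mobile row
  trunc <- pair$a[pair$a$res_seq > 3, ]
  fit2 <- superpose(trunc, pair$a)
  aln2 <- structure_alignment(trunc, pair$a, fit2)
  expect_equal(substr(aln2$alignment[[1]], 1, 3), "---")
  expect_equal(nrow(aln2$pairs), 9)
  # crossings forbidden: pairing is strictly increasing on both sides
  expect_true(all(diff(aln2$pairs$res_mobile) > 0))
  expect_true(all(diff(aln2$pairs$res_target) > 0))

  # zero cutoff gives an empty alignment with a warning
  noisy <- simulate_structure_pair(10, angle = 0.3, noise_sd = 0.3, seed = 9)
  fit3 <- superpose(noisy$a, noisy$b)
  expect_warning(empty <- structure_alignment(noisy$a, noisy$b, fit3,
                                              pair_cutoff = 0))
  expect_equal(nrow(empty$pairs), 0)
})
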