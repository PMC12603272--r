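ref_ligand <- function() {
  data.frame(element = c("C", "C", "N", "O", "C"),
             x = c(0, 1.4, 2.6, 3.1, -1.2),
             y = c(0, 0.3, -0.5, 0.9, 1.1),
             z = c(0, 0.2, 0.8, -0.4, 0.5))
}

test_that("symmetry RMSD handles identity, translation and swaps", {
  r <- ref_ligand()
  expect_equal(symmetry_rmsd(r, r)$rmsd, 0, tolerance = 1e-12)

  shifted <- r; shifted$x <- shifted$x + 1
  expect_equal(symmetry_rmsd(shifted, r)$rmsd, 1.0, tolerance = 1e-12)

  # swapping two chemically equivalent carbons is symmetry-corrected away
  swapped <- r[c(2, 1, 3, 4, 5), ]
  ev <- symmetry_rmsd(swapped, r)
  expect_equal(ev$rmsd, 0, tolerance = 1e-12)
  expect_equal(ev$matched_permutation, c(2L, 1L, 3L, 4L, 5L))
})

test_that("symmetry RMSD equals the exhaustive permutation minimum", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    el <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
    pc <- matrix(rnorm(n * 3, sd = 2), n, 3)
    rc <- matrix(rnorm(n * 3, sd = 2), n, 3)
    ours <- symmetry_rmsd(data.frame(element = el, x = pc[, 1], y = pc[, 2],
                                     z = pc[, 3]),
                          data.frame(element = el, x = rc[, 1], y = rc[, 2],
                                     z = rc[, 3]))$rmsd
    oracle <- brute_force_symmetry_rmsd(el, pc, el, rc)
    expect_equal(ours, oracle, tolerance = 1e-9)
  }
})

test_that("symmetry RMSD never exceeds the same-order RMSD", {
  set.seed(42)
  r <- ref_ligand()
  for (rep in 1:10) {
    p <- r
    p$x <- p$x + rnorm(5); p$y <- p$y + rnorm(5); p$z <- p$z + rnorm(5)
    naive <- sqrt(mean((p$x - r$x)^2 + (p$y - r$y)^2 + (p$z - r$z)^2))
    expect_lte(symmetry_rmsd(p, r)$rmsd, naive + 1e-12)
  }
})

test_that("symmetry RMSD validates atom counts and elements", {
  r <- ref_ligand()
  expect_error(symmetry_rmsd(r[1:3, ], r), "atom-count mismatch")
  wrong <- r; wrong$element[1] <- "S"
  expect_error(symmetry_rmsd(wrong, r), "element multisets")
})

test_that("docking accuracy counts threshold successes", {
  expect_equal(docking_accuracy(c(0.5, 1.2, 1.9), 2), 1)
  expect_equal(docking_accuracy(c(1, 3), 2), 0.5)
  expect_error(docking_accuracy(numeric(0), 2), "empty")
  expect_error(docking_accuracy(c(1, 2), 0), "positive")
})

test_that("docking accuracy is monotone in threshold, order-invariant", {
  set.seed(43)
  for (rep in 1:100) {
    rmsds <- runif(sample(3:30, 1), 0, 6)
    ths <- sort(runif(5, 0.1, 6))
    accs <- vapply(ths, function(t) docking_accuracy(rmsds, t), numeric(1))
    expect_true(all(diff(accs) >= 0))
    expect_equal(docking_accuracy(sample(rmsds), ths[3]),
                 docking_accuracy(rmsds, ths[3]))
  }
})

test_that("score-affinity correlation matches the textbook formula", {
  scores <- c(-8.1, -7.2, -9.0, -6.5, -7.7)
  pkds <- c(7.5, 6.8, 8.2, 6.1, 7.0)
  out <- score_affinity_correlation(scores, pkds)
  cov_xy <- sum((scores - mean(scores)) * (pkds - mean(pkds))) / 4
  r_manual <- cov_xy / (sd(scores) * sd(pkds))
  expect_equal(out$pearson, r_manual, tolerance = 1e-12)
  # perfect anticorrelation
  expect_equal(score_affinity_correlation(-2 * pkds, pkds)$pearson, -1,
               tolerance = 1e-12)
  expect_error(score_affinity_correlation(rep(1, 5), pkds), "constant")
})

test_that("independent scores rarely show |r| above 0.5 at n = 27", {
  set.seed(44)
  hits <- 0
  for (b in 1:200) {
    r <- cor(rnorm(27), rnorm(27))
    if (abs(r) < 0.5) hits <- hits + 1
  }
  expect_gte(hits, 190)
})

test_that("pK_D / K_D conversions match hand arithmetic and invert", {
  expect_equal(pkd_to_kd(9), 1.0, tolerance = 1e-12)
  expect_equal(pkd_to_kd(7.59), 25.70, tolerance = 5e-4)
  expect_equal(pkd_to_kd(6.54), 288.4, tolerance = 5e-4)
  xs <- seq(4, 12, by = 0.5)
  expect_equal(kd_to_pkd(pkd_to_kd(xs)), xs, tolerance = 1e-12)
  expect_error(kd_to_pkd(-1), "positive")
  expect_error(pkd_to_kd(Inf), "finite")
})

test_that("rescoring averages per-model predictions arithmetically", {
  # the mean of the two printed range endpoints
  expect_equal(mean(c(6.54, 7.59)), 7.065)

  ds <- make_synthetic_complexes(n = 10, noise_sd = 0, seed = 3)
  dm <- assemble_descriptor_matrix(ds$records, ds$truth$grid)
  rp <- run_protocols(dm, split_seed = 1)
  models <- lapply(rp, function(r) r$model)

  lig <- ds$records[[2]]$structure$atoms
  lig <- lig[lig$is_ligand, ]
  p <- pose(lig, pose_id = "crystal", engine = "none")
  res <- rescore_pose(models, p, dm)
  expect_true(min(res$per_model_pkd) <= res$mean_pkd + 1e-12)
  expect_true(max(res$per_model_pkd) >= res$mean_pkd - 1e-12)
  expect_gt(res$kd_nM, 0)
  expect_equal(res$kd_nM, pkd_to_kd(res$mean_pkd))

  # identical models collapse to the single-model prediction
  res1 <- rescore_pose(list(models$model1, models$model1), p, dm)
  single <- predict(models$model1,
                    descriptor_row(dm, ds$records[[2]]$structure))
  expect_equal(res1$mean_pkd, unname(single), tolerance = 1e-12)
})

test_that("rescoring the crystal pose reproduces the training prediction", {
  ds <- make_synthetic_complexes(n = 12, noise_sd = 0.1, seed = 9)
  dm <- assemble_descriptor_matrix(ds$records, ds$truth$grid)
  rp <- run_protocols(dm, split_seed = 4)
  i <- 5
  lig <- ds$records[[i]]$structure$atoms
  lig <- lig[lig$is_ligand, ]
  res <- rescore_pose(list(rp$model1$model),
                      pose(lig, pose_id = "crystal"), dm)
  expect_equal(res$mean_pkd, unname(predict(rp$model1$model, dm$X[i, ])),
               tolerance = 1e-9)
})

test_that("rescoring rejects mismatched descriptor layouts", {
  ds <- make_synthetic_complexes(n = 8, seed = 5)
  dm <- assemble_descriptor_matrix(ds$records, ds$truth$grid)
  m_wrong <- fit_pls(matrix(rnorm(40), 8, 5), ds$truth$noiseless_pkd[1:8], 2)
  lig <- ds$records[[1]]$structure$atoms
  lig <- lig[lig$is_ligand, ]
  expect_error(rescore_pose(list(m_wrong), pose(lig), dm),
               "layout mismatch")
})

test_that("SDF ligands parse with coordinates, charges and scores", {
  sdf_text <- c(
    "lig1", "  groovebind", "",
    " 3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.1000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0", "  2  3  1  0  0  0  0", "M  END",
    ">  <PARTIAL_CHARGES>", "0.1 -0.25 0.15", "",
    ">  <ENGINE_SCORE>", "-7.4", "", "$$$$")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf_text, f)
  poses <- read_ligand_sdf(f, engine = "smina/vinardo")
  expect_length(poses, 1L)
  p <- poses[[1]]
  expect_equal(p$atoms$element, c("C", "N", "O"))
  expect_equal(p$atoms$x, c(0, 1.4, 2.1))
  expect_equal(p$atoms$charge, c(0.1, -0.25, 0.15))
  expect_equal(p$engine_score, -7.4)
  expect_error(read_ligand_sdf("nope.sdf"), "not found")
})
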