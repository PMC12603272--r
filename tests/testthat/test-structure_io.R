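test_that("read_complex partitions ligand and receptor atoms", {
  cs <- read_complex(tiny_pdb_lines(), ligand_resnames = "LIG",
                     charges_from = "occupancy")
  expect_s3_class(cs, "complex_structure")
  expect_equal(sum(cs$atoms$is_ligand), 1L)
  expect_equal(sum(!cs$atoms$is_ligand), 2L)
  expect_equal(cs$atoms$charge[cs$atoms$is_ligand], 0.25)
  expect_equal(cs$atoms$x[1], 1.000, tolerance = 1e-9)
})

test_that("read_complex errors usefully on bad input", {
  expect_error(read_complex(tiny_pdb_lines(), ligand_resnames = "XYZ"),
               "empty ligand")
  expect_error(read_complex(tiny_pdb_lines(), character(0)), "non-empty")
  bad <- tiny_pdb_lines()
  substr(bad[2], 31, 38) <- "999x.999"
  expect_error(read_complex(bad, "LIG"), "line 2")
})

test_that("alternate locations other than blank/A are dropped", {
  pdb_line <- function(type, serial, name, alt, resname, chain, resno,
                       x, y, z) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, alt, resname, chain, resno, x, y, z,
            1, 0, toupper(substr(name, 1, 1)))
  }
  lines <- c(
    pdb_line("ATOM", 1, "P", "A", "DA", "A", 1, 1, 2, 3),
    pdb_line("ATOM", 2, "P", "B", "DA", "A", 1, 9, 9, 9),
    pdb_line("HETATM", 3, "C1", " ", "LIG", "X", 1, 0, 0, 0),
    "END"
  )
  cs <- read_complex(lines, "LIG")
  expect_equal(nrow(cs$atoms), 2L)
  expect_false(any(cs$atoms$x == 9))
})

test_that("write/read round trip preserves structure to PDB precision", {
  cs <- toy_complex()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex(cs, f, charges_to = "occupancy")
  back <- read_complex(f, "LIG", charges_from = "occupancy")
  expect_equal(coords(back), coords(cs), tolerance = 1e-9)  # 0.001 A grid
  expect_equal(back$atoms$element, cs$atoms$element)
  expect_equal(back$atoms$resno, cs$atoms$resno)
  expect_equal(back$atoms$is_ligand, cs$atoms$is_ligand)
})

test_that("lock/key split conserves atoms and coordinates exactly", {
  cs <- toy_complex()
  parts <- split_lock_key(cs)
  expect_equal(nrow(parts$receptor$atoms) + nrow(parts$ligand$atoms),
               nrow(cs$atoms))
  expect_false(any(parts$receptor$atoms$is_ligand))
  expect_true(all(parts$ligand$atoms$is_ligand))
  merged <- merge_lock_key(parts$receptor, parts$ligand)
  key <- function(a) sort(paste(a$name, a$x, a$y, a$z))
  expect_equal(key(merged$atoms), key(cs$atoms))

  all_rec <- cs
  all_rec$atoms$is_ligand <- FALSE
  expect_error(split_lock_key(all_rec), "empty ligand")
})

test_that("superposition recovers identity, translations and rotations", {
  cs <- toy_complex()
  sp0 <- superpose_backbone(cs, cs)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(sp0$translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)

  moved <- rigidly_move(cs, diag(3), c(1, 2, 3))
  sp1 <- superpose_backbone(moved, cs)
  expect_equal(sp1$translation, c(-1, -2, -3), tolerance = 1e-9)
  expect_equal(sp1$rmsd, 0, tolerance = 1e-9)

  R30 <- rotation_about_z(30)
  rot <- rigidly_move(cs, R30, c(0, 0, 0))
  sp2 <- superpose_backbone(rot, cs)
  expect_lt(sp2$rmsd, 1e-8)
  expect_equal(sp2$rotation %*% R30, diag(3), tolerance = 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-10)

  # ligand atoms ride along with the same rigid motion
  aligned <- apply_superposition(rot, sp2)
  expect_equal(coords(aligned, "ligand"), coords(cs, "ligand"),
               tolerance = 1e-8)
})

test_that("superposition errors on too few or collinear matches", {
  cs <- toy_complex()
  expect_error(superpose_backbone(cs, cs, backbone_names = "P"),
               "fewer than 3")
  line <- cs
  bbsel <- !line$atoms$is_ligand
  line$atoms$x[bbsel] <- seq_len(sum(bbsel))
  line$atoms$y[bbsel] <- 0
  line$atoms$z[bbsel] <- 0
  expect_error(superpose_backbone(line, line), "collinear")
})

test_that("Kabsch matches brute-force quaternion minimization", {
  set.seed(5)
  for (rep in 1:3) {
    p <- matrix(rnorm(5 * 3, sd = 2), 5, 3)
    q <- matrix(rnorm(5 * 3, sd = 2), 5, 3)
    kb <- groovebind:::kabsch(p, q)
    fitted <- sweep(p %*% t(kb$rotation), 2, kb$translation, `+`)
    rmsd_kabsch <- sqrt(mean(rowSums((fitted - q)^2)))
    expect_equal(rmsd_kabsch, brute_force_superpose_rmsd(p, q),
                 tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD agrees with the bio3d fitting oracle", {
  set.seed(9)
  p <- matrix(rnorm(12 * 3, sd = 3), 12, 3)
  q <- matrix(rnorm(12 * 3, sd = 3), 12, 3)
  kb <- groovebind:::kabsch(p, q)
  fitted <- sweep(p %*% t(kb$rotation), 2, kb$translation, `+`)
  ours <- sqrt(mean(rowSums((fitted - q)^2)))
  xyz_fit <- bio3d::fit.xyz(as.vector(t(q)), as.vector(t(p)),
                            fixed.inds = 1:36, mobile.inds = 1:36)
  theirs <- bio3d::rmsd(as.vector(t(q)), xyz_fit)
  expect_equal(ours, theirs, tolerance = 1e-4)
})

test_that("superposition RMSD is invariant under a common rigid motion", {
  cs <- toy_complex()
  set.seed(21)
  other <- rigidly_move(cs, rotation_about_z(40), c(0.3, -0.2, 0.7))
  other$atoms$x <- other$atoms$x + rnorm(nrow(other$atoms), 0, 0.2)
  base <- superpose_backbone(other, cs)$rmsd
  R <- rotation_about_z(77); shift <- c(5, -3, 11)
  both <- superpose_backbone(rigidly_move(other, R, shift),
                             rigidly_move(cs, R, shift))$rmsd
  expect_equal(base, both, tolerance = 1e-9)
})

test_that("align_dataset brings all complexes onto the reference frame", {
  ds <- make_synthetic_complexes(n = 5, seed = 4)
  recs <- ds$records
  # scatter records with arbitrary rigid motions, then re-align
  set.seed(14)
  for (i in seq_along(recs))
    recs[[i]]$structure <- rigidly_move(recs[[i]]$structure,
                                        rotation_about_z(runif(1, 0, 360)),
                                        rnorm(3, sd = 8))
  out <- align_dataset(recs)
  expect_true(all(out$alignment_rmsd < 1e-6))
  # all receptors share the decamer, so after alignment they coincide
  # with the reference's receptor
  expect_equal(coords(out$records[[3]]$structure, "receptor"),
               coords(recs[[1]]$structure, "receptor"), tolerance = 1e-6)
  # the rigid motion preserves each ligand's pose relative to its DNA
  dists <- function(cs) as.vector(dist(coords(cs)))
  expect_equal(dists(out$records[[3]]$structure),
               dists(ds$records[[3]]$structure), tolerance = 1e-9)
})

test_that("complex_record derives pkd from kd and validates", {
  cs <- toy_complex()
  r <- complex_record(cs, kd = 1e-7, ligand_id = "HOECHST")
  expect_equal(r$pkd, 7)
  expect_lt(abs(r$pkd + log10(r$kd)), 1e-9)
  expect_error(complex_record(cs, kd = 0, ligand_id = "x"), "positive")
})

test_that("manifest reading validates columns and kd", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(complex_id = "c1", pdb_id = "c1.pdb",
                       ligand_id = "l1", kd_molar = 1e-8),
            f, row.names = FALSE)
  m <- read_manifest(f)
  expect_equal(m$kd_molar, 1e-8)
  write.csv(data.frame(a = 1), f, row.names = FALSE)
  expect_error(read_manifest(f), "missing columns")
  expect_error(read_manifest("no/such/file.csv"), "not found")
})
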