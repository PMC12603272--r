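# Synthetic receptor: an idealized double-helical decamer backbone.
# Two antiparallel strands of 10 residues; each residue carries the six
# standard backbone atoms on a helix of ~9.4 A radius, 36 deg twist and
# 3.38 A rise, roughly B-form dimensions. Geometry is schematic: it gives
# the superposition and lock/key machinery realistic atom names, chains
# and residue numbering, not real DNA stereochemistry.
synthetic_decamer <- function() {
  offsets <- list(  # per-atom local displacements within a residue
    "P"   = c(0.0, 0.0, 0.0),
    "O5'" = c(0.5, 0.4, 0.5),
    "C5'" = c(1.0, 0.0, 1.0),
    "C4'" = c(1.4, -0.5, 1.4),
    "C3'" = c(1.2, -1.0, 2.0),
    "O3'" = c(0.6, -1.2, 2.6)
  )
  rows <- list()
  for (strand in 1:2) {
    chain <- c("A", "B")[strand]
    dir <- if (strand == 1) 1 else -1
    phase <- if (strand == 1) 0 else 2.4  # minor-groove-ish offset
    for (res in 1:10) {
      theta <- dir * (res - 1) * 36 * pi / 180 + phase
      base <- c(9.4 * cos(theta), 9.4 * sin(theta), dir * (res - 1) * 3.38)
      for (nm in names(offsets)) {
        p <- base + offsets[[nm]]
        rows[[length(rows) + 1L]] <- data.frame(
          element = substr(nm, 1, 1), name = nm, chain = chain,
          resno = res, resname = c("DA", "DT")[strand], insert = "",
          x = p[1], y = p[2], z = p[3], charge = 0, occ = 0, b = 0,
          is_ligand = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Shared ligand scaffold: n_sites point-atom positions on odd-integer
# offsets from the scaffold center with pairwise separation >= 4 A. The
# truth grid places its points on even offsets, so every site sits at
# least sqrt(3) A from any grid point and, with the charge range used, no
# field value ever reaches the clamp: the electrostatic descriptor block
# is then exactly linear in the per-ligand charges.
scaffold_sites <- function(n_sites, center) {
  cand <- as.matrix(expand.grid(x = c(-5, -3, -1, 1, 3, 5),
                                y = c(-5, -3, -1, 1, 3, 5),
                                z = c(-5, -3, -1, 1, 3, 5)))
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  chosen <- cand[1, , drop = FALSE]
  for (i in 2:nrow(cand)) {
    if (nrow(chosen) == n_sites) break
    d <- sqrt(rowSums(sweep(chosen, 2, cand[i, ])^2))
    if (all(d >= 4)) chosen <- rbind(chosen, cand[i, ])
  }
  if (nrow(chosen) < n_sites)
    stop("could not place ", n_sites, " scaffold sites")
  sweep(chosen, 2, center, `+`)
}

scaffold_atoms <- function(scaffold, charges) {
  n <- nrow(scaffold$sites)
  data.frame(
    element = scaffold$elements, name = paste0("L", seq_len(n)),
    chain = "X", resno = 1L, resname = "LIG", insert = "",
    x = scaffold$sites[, 1], y = scaffold$sites[, 2],
    z = scaffold$sites[, 3],
    charge = charges, occ = 0, b = 0, is_ligand = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic aligned complex dataset with known truth
#'
#' Emulates the study design the QSAR stage assumes: a panel of
#' ligand/DNA-decamer complexes sharing one aligned frame, each with a
#' measured dissociation constant. The panel varies a shared scaffold of
#' `n_sites` point atoms (C/N/O) by drawing per-ligand partial charges;
#' noiseless pK_D is linear in a sparse set of electrostatic field-grid
#' columns, affinely rescaled to span `pkd_range`, and Gaussian noise of
#' SD `noise_sd` is added. Scaffold sites sit mid-cell on the truth grid
#' and charges stay within `charge_range`, so no field value clamps and
#' the descriptor matrix is exactly linear in the charges -- which makes
#' the noiseless pK_D exactly recoverable by PLS, the property the
#' validation tests rely on. A few records share a `ligand_id` (the same
#' ligand bound in a second complex), mirroring the duplicated ligands
#' real minor-groove panels contain.
#'
#' @param n number of complexes (>= 5; default 27).
#' @param n_sites number of scaffold atoms (default 6).
#' @param n_informative number of electrostatic grid columns with nonzero
#'   true coefficients.
#' @param noise_sd SD of the pK_D noise, pK_D units.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param pkd_range target span of the noiseless pK_D values.
#' @param charge_range per-site partial-charge range, elementary charges.
#' @param params [probe_params()] used for the truth's field rows.
#' @param n_duplicated how many ligands appear in two complexes (same
#'   ligand_id and coordinates; affinities differ through the noise).
#' @return list with `records` (list of `complex_record`) and `truth`
#'   (class `synthetic_truth`: `true_coefficients` over unfiltered grid
#'   columns, rescale slope/intercept, `noise_sd`, `seed`, `pkd_range`,
#'   `grid`, `params`, `scaffold`, `noiseless_pkd`).
#' @export
make_synthetic_complexes <- function(n = 27, n_sites = 6,
                                     n_informative = 6, noise_sd = 0.15,
                                     seed = 1, pkd_range = c(5, 9),
                                     charge_range = c(-0.12, 0.12),
                                     params = probe_params(),
                                     n_duplicated = 2) {
  if (n < 5L) stop("need n >= 5")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  receptor <- synthetic_decamer()
  center <- c(0, 0, 0)  # helix axis, mid-height of the duplex
  sites <- scaffold_sites(n_sites, center)
  scaffold <- list(
    sites = sites,
    elements = sample(c("C", "N", "O"), n_sites, replace = TRUE,
                      prob = c(0.6, 0.2, 0.2))
  )
  grid <- grid_spec(origin = center - 8, spacing = 2, dims = c(9, 9, 9))

  n_base <- n - n_duplicated
  if (n_base < 3L) stop("n_duplicated too large for n")
  charges <- lapply(seq_len(n_base), function(i)
    runif(n_sites, charge_range[1], charge_range[2]))
  dup_src <- sample(seq_len(n_base), n_duplicated)
  charges <- c(charges, charges[dup_src])
  ligand_ids <- c(sprintf("LIG%02d", seq_len(n_base)),
                  sprintf("LIG%02d", dup_src))

  structures <- lapply(seq_len(n), function(i)
    complex_structure(rbind(receptor, scaffold_atoms(scaffold, charges[[i]])),
                      complex_id = sprintf("CPX%02d", i),
                      source = "synthetic"))

  rows <- t(vapply(structures, function(s) {
    fg <- compute_probe_energies(s, grid, params)
    c(fg$steric, fg$electrostatic)
  }, numeric(2 * prod(grid$dims))))
  n_pts <- prod(grid$dims)
  elec_cols <- n_pts + seq_len(n_pts)
  if (max(abs(rows[, elec_cols])) >= params$cap)
    stop("electrostatic field reached the clamp; charge_range too wide")

  informative <- elec_cols[order(apply(rows[, elec_cols], 2, sd),
                                 decreasing = TRUE)[
                                   seq_len(min(n_informative, n_pts))]]
  w <- numeric(ncol(rows))
  w[informative] <- rnorm(length(informative))
  raw <- drop(rows %*% w)
  if (diff(range(raw)) < 1e-9)
    stop("degenerate field rows: cannot rescale pK_D")
  a <- diff(pkd_range) / diff(range(raw))
  b <- pkd_range[1] - a * min(raw)
  pkd_clean <- a * raw + b
  pkd <- pkd_clean + rnorm(n, 0, noise_sd)

  records <- lapply(seq_len(n), function(i)
    complex_record(structures[[i]], kd = 10^(-pkd[i]),
                   ligand_id = ligand_ids[i]))
  truth <- structure(list(
    true_coefficients = w, rescale_slope = a, rescale_intercept = b,
    noise_sd = noise_sd, seed = seed, pkd_range = pkd_range,
    charge_range = charge_range, grid = grid, params = params,
    scaffold = scaffold, noiseless_pkd = pkd_clean, receptor = receptor
  ), class = "synthetic_truth")
  list(records = records, truth = truth)
}

#' Generate a fresh synthetic ligand under an existing truth
#'
#' Draws new charges on the truth's scaffold and returns the complex with
#' its noiseless pK_D under the truth's coefficients and rescaling, for
#' held-out prediction tests.
#'
#' @param truth a `synthetic_truth` from [make_synthetic_complexes()].
#' @param seed integer seed.
#' @param ligand_id identifier for the new ligand.
#' @return list with `structure` (a `complex_structure`), `pkd_true`
#'   (noiseless) and `ligand_id`.
#' @export
synthetic_holdout <- function(truth, seed = 99, ligand_id = "HOLDOUT") {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  q <- runif(nrow(truth$scaffold$sites), truth$charge_range[1],
             truth$charge_range[2])
  s <- complex_structure(rbind(truth$receptor,
                               scaffold_atoms(truth$scaffold, q)),
                         complex_id = ligand_id, source = "synthetic")
  fg <- compute_probe_energies(s, truth$grid, truth$params)
  raw <- sum(c(fg$steric, fg$electrostatic) * truth$true_coefficients)
  list(structure = s,
       pkd_true = truth$rescale_slope * raw + truth$rescale_intercept,
       ligand_id = ligand_id)
}

#' Generate poses at controlled RMSD from a reference
#'
#' Each pose is the reference rigidly translated along a random direction
#' by the target distance; a uniform translation of magnitude d has RMSD
#' exactly d, so the construction hits each target to machine precision.
#'
#' @param reference a `pose` (or ligand `complex_structure`).
#' @param target_rmsds numeric vector of target RMSDs, Angstrom (>= 0).
#' @param seed integer seed for the translation directions.
#' @param engine engine label stamped on the poses.
#' @return list of `pose`s.
#' @export
make_pose_set <- function(reference, target_rmsds, seed = 1,
                          engine = "synthetic") {
  if (any(target_rmsds < 0)) stop("target_rmsds must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xyz <- pose_coords(reference)
  el <- pose_elements(reference)
  charge <- if (inherits(reference, "pose")) reference$atoms$charge
  else if (inherits(reference, "complex_structure"))
    reference$atoms$charge[reference$atoms$is_ligand]
  else rep(0, nrow(xyz))
  lapply(seq_along(target_rmsds), function(i) {
    d <- target_rmsds[i]
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    shifted <- sweep(xyz, 2, d * u, `+`)
    pose(data.frame(element = el, x = shifted[, 1], y = shifted[, 2],
                    z = shifted[, 3], charge = charge,
                    stringsAsFactors = FALSE),
         pose_id = sprintf("pose%02d", i), engine = engine,
         engine_score = NA_real_)
  })
}

#' Generate a panel of synthetic titrations
#'
#' Mirrors the photoluminescence titration design: ligand held at 10 uM,
#' dsDNA titrated from 0 to 10 uM in 0.5 uM steps, 2% multiplicative
#' noise.
#'
#' @param kds vector of dissociation constants, mol/L.
#' @param seed integer seed (incremented per series).
#' @param l_total ligand concentration, mol/L.
#' @param dna_max top dsDNA concentration, mol/L.
#' @param dna_step titration step, mol/L.
#' @param fmax,f0 amplitude and baseline, intensity units.
#' @param noise_cv multiplicative noise CV.
#' @return list of `titration_series`.
#' @export
make_titration_panel <- function(kds, seed = 1, l_total = 1e-5,
                                 dna_max = 1e-5, dna_step = 5e-7,
                                 fmax = 1000, f0 = 10, noise_cv = 0.02) {
  if (any(!is.finite(kds) | kds <= 0)) stop("kds must be positive")
  dna <- seq(0, dna_max, by = dna_step)
  lapply(seq_along(kds), function(i)
    simulate_titration(l_total, dna, kds[i], fmax = fmax, f0 = f0,
                       noise_cv = noise_cv, seed = seed + i - 1L))
}

#' Write a synthetic dataset as PDB files plus a manifest CSV
#'
#' Emits the same on-disk formats the real pipeline reads (one PDB per
#' complex, partial charges in the occupancy column, and a manifest CSV
#' with complex_id/pdb_id/ligand_id/kd_molar), so fixtures exercise the
#' parsers.
#'
#' @param dataset result of [make_synthetic_complexes()].
#' @param dir output directory (created if needed).
#' @return path to the manifest CSV, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$records, function(r) {
    id <- r$structure$complex_id
    write_complex(r$structure, file.path(dir, paste0(id, ".pdb")),
                  charges_to = "occupancy")
    data.frame(complex_id = id, pdb_id = paste0(id, ".pdb"),
               ligand_id = r$ligand_id, kd_molar = r$kd,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
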