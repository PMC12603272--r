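#' Validated run configuration
#'
#' Collects every tunable of the pipeline in one validated object that is
#' serialized into each output for provenance.
#'
#' @param manifest path to the dataset manifest CSV (see
#'   [read_manifest()]); the PDB files it names are resolved relative to
#'   its directory.
#' @param out_dir output directory.
#' @param ligand_resnames residue names identifying ligands in PDB input.
#' @param grid_spacing,grid_padding field-grid geometry, Angstrom.
#' @param min_sigma descriptor column SD filter, kcal/mol.
#' @param max_components upper bound for PLS component selection.
#' @param split_seed,test_fraction protocol-2 split parameters.
#' @param rmsd_threshold redocking success threshold, Angstrom.
#' @param seed master seed for synthetic stages.
#' @param reference_id alignment reference complex (default first).
#' @return list of class `run_config`.
#' @export
run_config <- function(manifest = NULL, out_dir = ".",
                       ligand_resnames = "LIG", grid_spacing = 2,
                       grid_padding = 4, min_sigma = 0.05,
                       max_components = 8, split_seed = 1,
                       test_fraction = 0.2, rmsd_threshold = 2,
                       seed = 1, reference_id = NULL) {
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (grid_padding < 0) stop("grid_padding must be >= 0")
  if (min_sigma < 0) stop("min_sigma must be >= 0")
  if (max_components < 1) stop("max_components must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  if (rmsd_threshold <= 0) stop("rmsd_threshold must be positive")
  structure(list(manifest = manifest, out_dir = out_dir,
                 ligand_resnames = ligand_resnames,
                 grid_spacing = grid_spacing, grid_padding = grid_padding,
                 min_sigma = min_sigma, max_components = max_components,
                 split_seed = split_seed, test_fraction = test_fraction,
                 rmsd_threshold = rmsd_threshold, seed = seed,
                 reference_id = reference_id),
            class = "run_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[groovebind] %s: %s", stage, sprintf(...)))
}

config_provenance <- function(config) {
  cfg <- unclass(config)
  cfg$reference_id <- if (is.null(cfg$reference_id)) "" else cfg$reference_id
  cfg$manifest <- if (is.null(cfg$manifest)) "" else cfg$manifest
  cfg
}

# Atomic write: build in a temp file, then rename into place.
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Generate the synthetic fixture tree
#'
#' Writes a complete synthetic input set (PDB complexes with charges in
#' the occupancy column, manifest CSV) under `out_dir`, suitable as input
#' for [cmd_build_dataset()] and [cmd_fit()].
#'
#' @param config a [run_config()]; `seed` controls the generator.
#' @param n number of complexes.
#' @param noise_sd pK_D noise SD.
#' @return path to the written manifest, invisibly.
#' @export
cmd_simulate <- function(config, n = 27, noise_sd = 0.15) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage("simulate", "n=%d noise_sd=%.3f seed=%d", n, noise_sd,
            config$seed)
  ds <- make_synthetic_complexes(n = n, noise_sd = noise_sd,
                                 seed = config$seed)
  path <- write_synthetic_dataset(ds, config$out_dir)
  jsonlite::write_json(config_provenance(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load, align and split a complex dataset
#'
#' Reads the manifest and its PDB files, superposes every complex onto the
#' reference via the DNA backbone, and writes per-complex lock ("-lock.pdb",
#' DNA) and key ("-key.pdb", ligand) files plus an alignment report.
#'
#' @param config a [run_config()] with `manifest` set.
#' @return list with `records` (aligned `complex_record`s) and
#'   `alignment_rmsd`, invisibly.
#' @export
cmd_build_dataset <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$manifest)) stop("config$manifest is required")
  manifest <- read_manifest(config$manifest)
  base <- dirname(config$manifest)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    cs <- read_complex(file.path(base, m$pdb_id),
                       ligand_resnames = config$ligand_resnames,
                       complex_id = m$complex_id, source = m$pdb_id,
                       charges_from = "occupancy")
    complex_record(cs, kd = m$kd_molar, ligand_id = m$ligand_id)
  })
  aligned <- align_dataset(records, reference_id = config$reference_id)
  log_stage("build-dataset", "%d complexes aligned (max backbone RMSD %.3f A)",
            length(aligned$records), max(aligned$alignment_rmsd))
  for (r in aligned$records) {
    parts <- split_lock_key(r$structure)
    id <- r$structure$complex_id
    write_complex(parts$receptor,
                  file.path(config$out_dir, paste0(id, "-lock.pdb")))
    write_complex(parts$ligand,
                  file.path(config$out_dir, paste0(id, "-key.pdb")),
                  charges_to = "occupancy")
  }
  report <- data.frame(complex_id = names(aligned$alignment_rmsd),
                       alignment_rmsd = unname(aligned$alignment_rmsd))
  write_atomic(function(p) utils::write.csv(report, p, row.names = FALSE),
               file.path(config$out_dir, "alignment.csv"))
  invisible(aligned)
}

#' Fit the three QSAR protocols on an aligned dataset
#'
#' Assembles the descriptor matrix and runs the three model protocols;
#' writes a validation-report CSV and a JSON serialization of the fitted
#' models.
#'
#' @param config a [run_config()].
#' @param records aligned `complex_record`s (from [cmd_build_dataset()]);
#'   if NULL they are built from `config$manifest`.
#' @return list with `reports` (a `protocol_reports`) and `descriptors`,
#'   invisibly.
#' @export
cmd_fit <- function(config, records = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(records)) records <- cmd_build_dataset(config)$records
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- grid_for_dataset(records, config$grid_spacing,
                           config$grid_padding)
  descriptors <- assemble_descriptor_matrix(records, grid,
                                            min_sigma = config$min_sigma)
  log_stage("fit", "descriptor matrix %d x %d (of %d columns)",
            nrow(descriptors$X), ncol(descriptors$X),
            length(descriptors$kept_mask))
  reports <- run_protocols(descriptors, split_seed = config$split_seed,
                           test_fraction = config$test_fraction,
                           max_components = config$max_components)
  stats_rows <- do.call(rbind, lapply(reports, function(r) {
    s <- r$stats
    data.frame(protocol = r$protocol, n_components = r$model$n_components,
               r2 = s$r2, q2 = s$q2, sdep = s$sdep,
               q2_ext = if (is.null(s$q2_ext)) NA_real_ else s$q2_ext,
               sdep_ext = if (is.null(s$sdep_ext)) NA_real_ else s$sdep_ext)
  }))
  write_atomic(function(p) utils::write.csv(stats_rows, p, row.names = FALSE),
               file.path(config$out_dir, "validation.csv"))
  write_atomic(function(p) write_model_json(reports, descriptors, p),
               file.path(config$out_dir, "models.json"))
  invisible(list(reports = reports, descriptors = descriptors))
}

#' Rescore docked poses with fitted QSAR models
#'
#' @param config a [run_config()].
#' @param fit result of [cmd_fit()].
#' @param poses list of `pose`s.
#' @return the `rescoring_result`, invisibly; a per-pose CSV is written to
#'   `out_dir`.
#' @export
cmd_rescore <- function(config, fit, poses) {
  stopifnot(inherits(config, "run_config"))
  models <- lapply(fit$reports, function(r) r$model)
  res <- rescore_pose(models, poses, fit$descriptors)
  per_pose <- data.frame(
    pose_id = rownames(res$per_model_pkd),
    engine = vapply(poses, function(p) p$engine, character(1)),
    engine_score = vapply(poses, function(p) p$engine_score, numeric(1)),
    res$per_model_pkd,
    mean_pkd = rowMeans(res$per_model_pkd)
  )
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_atomic(function(p) utils::write.csv(per_pose, p, row.names = FALSE),
               file.path(config$out_dir, "rescoring.csv"))
  log_stage("rescore", "%d poses, mean pK_D %.3f (K_D %.1f nM)",
            length(poses), res$mean_pkd, res$kd_nM)
  invisible(res)
}

#' Fit a titration CSV
#'
#' Reads a two-column CSV (`dna_uM`, `intensity`), fits the tight-binding
#' model and the saturation breakpoint, and writes the result JSON.
#'
#' @param config a [run_config()].
#' @param csv path to the titration CSV.
#' @param ligand_total_uM constant ligand concentration, uM.
#' @return the `binding_fit`, invisibly.
#' @export
cmd_titrate <- function(config, csv, ligand_total_uM = 10) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(csv)) stop("titration CSV not found: ", csv)
  d <- utils::read.csv(csv)
  if (!all(c("dna_uM", "intensity") %in% names(d)))
    stop("titration CSV needs columns dna_uM, intensity")
  series <- titration_series(ligand_total_uM * 1e-6, d$dna_uM * 1e-6,
                             d$intensity)
  bf <- fit_titration(series)
  out <- list(kd_nM = bf$kd * 1e9, fmax = bf$fmax, f0 = bf$f0,
              saturation_ratio = bf$saturation_ratio,
              residual_sd = bf$residual_sd,
              config = config_provenance(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_atomic(function(p) jsonlite::write_json(out, p, auto_unbox = TRUE,
                                                digits = NA),
               file.path(config$out_dir, "titration_fit.json"))
  log_stage("titrate", "K_D %.1f nM, saturation %.2f dsDNA:ligand",
            bf$kd * 1e9, bf$saturation_ratio)
  invisible(bf)
}
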