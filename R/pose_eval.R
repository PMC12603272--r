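#' Construct a docked pose
#'
#' A pose holds one docked ligand conformation in the receptor frame,
#' together with the docking engine's label and score.
#'
#' @param atoms data.frame with at least `element`, `x`, `y`, `z` (and
#'   `charge` if the pose is to be rescored).
#' @param pose_id identifier.
#' @param engine engine/scoring-function label (e.g. "plants/chemplp",
#'   "smina/vinardo").
#' @param engine_score engine score, engine units.
#' @return object of class `pose`.
#' @export
pose <- function(atoms, pose_id = "pose", engine = "", engine_score = NA_real_) {
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0
  structure(list(pose_id = pose_id, engine = engine,
                 engine_score = engine_score,
                 atoms = as.data.frame(atoms, stringsAsFactors = FALSE)),
            class = "pose")
}

pose_coords <- function(p) {
  if (inherits(p, "pose")) unname(as.matrix(p$atoms[, c("x", "y", "z")]))
  else if (inherits(p, "complex_structure")) coords(p, "ligand")
  else unname(as.matrix(p[, c("x", "y", "z")]))
}

pose_elements <- function(p) {
  if (inherits(p, "pose")) p$atoms$element
  else if (inherits(p, "complex_structure"))
    p$atoms$element[p$atoms$is_ligand]
  else p$element
}

#' Symmetry-corrected RMSD between a pose and a reference ligand
#'
#' Docking-convention RMSD: the receptor frame is fixed (no refitting of a
#' rigid transform). Chemically equivalent atoms are handled by minimizing
#' over element-preserving atom correspondences, solved as an optimal
#' assignment (Hungarian algorithm) on squared distances within each
#' element class. Because the total squared deviation separates over
#' element classes, the per-class optimum is the global optimum over all
#' element-preserving permutations.
#'
#' @param pose a `pose` (or data.frame with element/x/y/z).
#' @param reference the reference ligand: a `pose`, `complex_structure`
#'   (its ligand atoms) or data.frame.
#' @return list of class `pose_evaluation` with `rmsd` (Angstrom) and
#'   `matched_permutation` (index map: pose atom i pairs with reference
#'   atom `matched_permutation[i]`).
#' @export
symmetry_rmsd <- function(pose, reference) {
  pc <- pose_coords(pose); pe <- pose_elements(pose)
  rc <- pose_coords(reference); re <- pose_elements(reference)
  if (nrow(pc) != nrow(rc))
    stop("atom-count mismatch: pose has ", nrow(pc), ", reference ", nrow(rc))
  if (!identical(sort(pe), sort(re)))
    stop("element multisets differ between pose and reference")
  n <- nrow(pc)
  perm <- integer(n)
  total_sq <- 0
  for (el in unique(pe)) {
    pi <- which(pe == el); ri <- which(re == el)
    if (length(pi) == 1L) {
      perm[pi] <- ri
      total_sq <- total_sq + sum((pc[pi, ] - rc[ri, ])^2)
    } else {
      cost <- outer(seq_along(pi), seq_along(ri), Vectorize(function(a, b)
        sum((pc[pi[a], ] - rc[ri[b], ])^2)))
      sol <- clue::solve_LSAP(cost)
      perm[pi] <- ri[as.integer(sol)]
      total_sq <- total_sq + sum(cost[cbind(seq_along(pi), as.integer(sol))])
    }
  }
  structure(list(rmsd = sqrt(total_sq / n), matched_permutation = perm),
            class = "pose_evaluation")
}

#' Redocking accuracy at an RMSD threshold
#'
#' Fraction of poses whose (symmetry-corrected) RMSD to the crystal pose is
#' at or below the threshold; the field-standard redocking success
#' criterion uses 2 Angstrom.
#'
#' @param rmsds numeric vector of RMSDs, Angstrom.
#' @param threshold success threshold, Angstrom.
#' @return fraction in \[0, 1\].
#' @export
docking_accuracy <- function(rmsds, threshold = 2) {
  if (length(rmsds) == 0L) stop("empty RMSD list")
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive")
  mean(rmsds <= threshold)
}

#' Correlation between engine scores and measured affinities
#'
#' @param engine_scores numeric vector of docking-engine scores.
#' @param pkds numeric vector of measured pK_D, same length.
#' @return list with `pearson` (product-moment r) and `spearman` (rank rho).
#' @export
score_affinity_correlation <- function(engine_scores, pkds) {
  if (length(engine_scores) != length(pkds) || length(pkds) < 3L)
    stop("need two equal-length vectors with at least 3 values")
  if (sd(engine_scores) == 0 || sd(pkds) == 0)
    stop("undefined correlation: constant vector")
  list(pearson = cor(engine_scores, pkds, method = "pearson"),
       spearman = cor(engine_scores, pkds, method = "spearman"))
}

#' Rescore docked poses with the QSAR models
#'
#' Uses the fitted 3D-QSAR models as an external scoring function: for each
#' pose, its field row is computed on the models' grid and every model
#' predicts a pK_D; the reported affinity is the unweighted arithmetic mean
#' over all (model, pose) pairs, converted to K_D in nM.
#'
#' @param models list of `pls_model`s sharing the descriptor layout (e.g.
#'   the three protocol models).
#' @param poses a `pose` or list of `pose`s whose atoms carry partial
#'   charges.
#' @param descriptors the `descriptor_matrix` the models were trained on
#'   (supplies grid, probe parameters and kept-column mask).
#' @return list of class `rescoring_result` with `per_model_pkd` (matrix,
#'   pose x model), `mean_pkd` and `kd_nM`.
#' @export
rescore_pose <- function(models, poses, descriptors) {
  if (inherits(models, "pls_model")) models <- list(models)
  if (inherits(poses, "pose")) poses <- list(poses)
  p_kept <- sum(descriptors$kept_mask)
  for (m in models)
    if (length(m$coefficients) != p_kept)
      stop("descriptor layout mismatch: model has ", length(m$coefficients),
           " columns, descriptors keep ", p_kept)
  rows <- lapply(poses, function(p) {
    a <- p$atoms
    a$is_ligand <- TRUE
    descriptor_row(descriptors, complex_structure(
      data.frame(element = a$element, name = a$element, chain = "",
                 resno = 1L, resname = "LIG", insert = "",
                 x = a$x, y = a$y, z = a$z, charge = a$charge,
                 occ = 0, b = 0, is_ligand = TRUE,
                 stringsAsFactors = FALSE),
      complex_id = p$pose_id))
  })
  per_model <- sapply(models, function(m)
    vapply(rows, function(r) predict(m, r), numeric(1)))
  per_model <- matrix(per_model, nrow = length(poses),
                      dimnames = list(
                        vapply(poses, function(p) p$pose_id, character(1)),
                        names(models)))
  mean_pkd <- mean(per_model)
  structure(list(per_model_pkd = per_model, mean_pkd = mean_pkd,
                 kd_nM = pkd_to_kd(mean_pkd)),
            class = "rescoring_result")
}

#' @export
print.rescoring_result <- function(x, ...) {
  cat(sprintf("<rescoring_result> %d pose(s) x %d model(s): mean pK_D = %.3f (K_D = %.1f nM)\n",
              nrow(x$per_model_pkd), ncol(x$per_model_pkd),
              x$mean_pkd, x$kd_nM))
  invisible(x)
}

#' Convert pK_D to K_D in nanomolar
#'
#' `K_D[nM] = 10^(-pK_D) * 1e9`.
#'
#' @param pkd numeric pK_D (dimensionless).
#' @return K_D in nM.
#' @export
pkd_to_kd <- function(pkd) {
  if (any(!is.finite(pkd))) stop("pkd must be finite")
  10^(-pkd) * 1e9
}

#' Convert K_D in nanomolar to pK_D
#'
#' @param kd_nM K_D in nM; must be positive.
#' @return pK_D.
#' @export
kd_to_pkd <- function(kd_nM) {
  if (any(!is.finite(kd_nM) | kd_nM <= 0)) stop("kd_nM must be positive")
  -log10(kd_nM * 1e-9)
}

#' Read a standalone ligand or pose set from an SDF file
#'
#' Parses a (multi-record) V2000 SDF via \pkg{ChemmineR}. Partial charges
#' are taken from a whitespace-separated data field (default
#' `PARTIAL_CHARGES`, one value per atom) when present, else zero. An
#' `ENGINE_SCORE` data field, when present, is stored as the engine score.
#'
#' @param file path to the SDF file.
#' @param charge_property name of the data field holding per-atom partial
#'   charges.
#' @param engine label stamped on the poses.
#' @return list of [pose()] objects, one per SDF record.
#' @export
read_ligand_sdf <- function(file, charge_property = "PARTIAL_CHARGES",
                            engine = "") {
  if (!file.exists(file)) stop("SDF file not found: ", file)
  sdfs <- ChemmineR::read.SDFset(file)
  lapply(seq_along(ChemmineR::cid(sdfs)), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    n <- nrow(ab)
    db <- ChemmineR::datablock(sdf)
    charge <- rep(0, n)
    if (charge_property %in% names(db)) {
      charge <- as.numeric(strsplit(trimws(db[[charge_property]]),
                                    "\\s+")[[1]])
      if (length(charge) != n)
        stop("charge field has ", length(charge), " values for ", n,
             " atoms")
    }
    score <- if ("ENGINE_SCORE" %in% names(db))
      as.numeric(db[["ENGINE_SCORE"]]) else NA_real_
    pose(data.frame(element = el, x = ab[, "C1"], y = ab[, "C2"],
                    z = ab[, "C3"], charge = charge,
                    stringsAsFactors = FALSE),
         pose_id = ChemmineR::sdfid(sdf), engine = engine,
         engine_score = score)
  })
}
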