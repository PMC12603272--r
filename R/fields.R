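# Coulomb constant in kcal*Angstrom/(mol*e^2)
COULOMB_K <- 332.06

# Lennard-Jones parameters (r_min Angstrom, well depth kcal/mol) by element.
LJ_PARAMS <- list(
  H  = c(rmin = 1.20, eps = 0.020),
  C  = c(rmin = 1.70, eps = 0.107),
  N  = c(rmin = 1.55, eps = 0.095),
  O  = c(rmin = 1.52, eps = 0.116),
  P  = c(rmin = 1.80, eps = 0.200),
  S  = c(rmin = 1.80, eps = 0.250),
  F  = c(rmin = 1.47, eps = 0.080),
  Cl = c(rmin = 1.75, eps = 0.250),
  Br = c(rmin = 1.85, eps = 0.320),
  I  = c(rmin = 1.98, eps = 0.400)
)

#' Define a rectilinear field grid
#'
#' @param origin 3-vector, Angstrom: coordinates of the first grid point.
#' @param spacing grid step in Angstrom (uniform in x, y, z).
#' @param dims 3 positive integers: number of points along each axis.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(dims) == 3L)
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  if (any(dims < 1L)) stop("dims must be >= 1")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %dx%dx%d points, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid enclosing a set of ligands
#'
#' Builds the smallest grid (at the given spacing) whose box encloses every
#' ligand atom of every record plus `padding` on each side.
#'
#' @param records list of `complex_record`s (or `complex_structure`s) in the
#'   common aligned frame.
#' @param spacing grid step, Angstrom.
#' @param padding margin added around the ligand bounding box, Angstrom.
#' @return a [grid_spec()].
#' @export
grid_for_dataset <- function(records, spacing = 2, padding = 4) {
  get_xyz <- function(r) {
    s <- if (inherits(r, "complex_record")) r$structure else r
    coords(s, "ligand")
  }
  xyz <- do.call(rbind, lapply(records, get_xyz))
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(origin = lo, spacing = spacing, dims = dims)
}

#' Coordinates of all grid points
#'
#' Points are ordered with x varying fastest, then y, then z (column-major
#' over the dims).
#'
#' @param grid a `grid_spec`.
#' @return numeric matrix (prod(dims) x 3), Angstrom.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + grid$spacing * (seq_len(grid$dims[k]) - 1))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  pts
}

#' Probe and field-evaluation parameters
#'
#' Defaults follow classical CoMFA practice: an sp3-carbon probe
#' (Lennard-Jones r_min 1.7 Angstrom, well depth 0.107 kcal/mol) carrying a
#' +1 e charge, energies clamped to +/- 30 kcal/mol, and a
#' distance-dependent dielectric eps(r) = r.
#'
#' @param probe_charge probe charge, elementary-charge units.
#' @param probe_rmin,probe_eps probe Lennard-Jones parameters (Angstrom,
#'   kcal/mol).
#' @param dielectric `"distance"` for eps(r) = r, or a positive number for a
#'   constant dielectric.
#' @param cap clamp for both field types, kcal/mol.
#' @param core_radius distance below which a grid point counts as inside an
#'   atom's core and receives +cap steric energy, Angstrom.
#' @return list of class `probe_params`.
#' @export
probe_params <- function(probe_charge = 1, probe_rmin = 1.7,
                         probe_eps = 0.107, dielectric = "distance",
                         cap = 30, core_radius = 0.3) {
  if (!identical(dielectric, "distance")) {
    dielectric <- as.numeric(dielectric)
    if (!is.finite(dielectric) || dielectric <= 0)
      stop("dielectric must be 'distance' or a positive number")
  }
  if (cap <= 0) stop("cap must be positive")
  structure(list(probe_charge = probe_charge, probe_rmin = probe_rmin,
                 probe_eps = probe_eps, dielectric = dielectric, cap = cap,
                 core_radius = core_radius),
            class = "probe_params")
}

#' Compute steric and electrostatic probe energies on a grid
#'
#' For each grid point p the electrostatic energy is the Coulomb sum
#' `k * q_probe * q_i / (eps(r_i) * r_i)` (k = 332.06 kcal*A/(mol*e^2)) and
#' the steric energy the Lennard-Jones 6-12 sum with combined probe/atom
#' parameters (Lorentz-Berthelot: r_min additive, well depth geometric
#' mean). Both are clamped to +/- cap; points inside an atom's core radius
#' get +cap steric energy.
#'
#' @param ligand a `complex_structure` whose ligand atoms carry partial
#'   charges, or a bare atoms data.frame.
#' @param grid a [grid_spec()].
#' @param params a [probe_params()].
#' @return list of class `field_grid` with `grid`, `steric`,
#'   `electrostatic` (numeric vectors of length prod(dims), kcal/mol).
#' @export
compute_probe_energies <- function(ligand, grid, params = probe_params()) {
  atoms <- if (inherits(ligand, "complex_structure")) {
    a <- ligand$atoms
    if (any(a$is_ligand)) a[a$is_ligand, , drop = FALSE] else a
  } else ligand
  if (nrow(atoms) == 0L) stop("no ligand atoms")
  el <- atoms$element
  unknown <- setdiff(unique(el), names(LJ_PARAMS))
  if (length(unknown) > 0L)
    stop("no Lennard-Jones parameters for element(s): ",
         paste(unknown, collapse = ", "))
  pts <- grid_points(grid)
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  lo <- grid$origin
  hi <- grid$origin + grid$spacing * (grid$dims - 1)
  if (any(apply(axyz, 2, min) < lo) || any(apply(axyz, 2, max) > hi))
    warning("grid box does not enclose all ligand atoms")

  n_pts <- nrow(pts)
  steric <- numeric(n_pts)
  elec <- numeric(n_pts)
  inside_core <- logical(n_pts)
  lj <- do.call(rbind, LJ_PARAMS[el])
  rmin_ij <- lj[, "rmin"] + params$probe_rmin
  eps_ij <- sqrt(lj[, "eps"] * params$probe_eps)
  qq <- COULOMB_K * params$probe_charge * atoms$charge

  for (j in seq_len(nrow(atoms))) {
    d2 <- (pts[, 1] - axyz[j, 1])^2 + (pts[, 2] - axyz[j, 2])^2 +
      (pts[, 3] - axyz[j, 3])^2
    r <- sqrt(pmax(d2, 1e-12))
    inside_core <- inside_core | r < params$core_radius
    sr6 <- (rmin_ij[j] / r)^6
    steric <- steric + eps_ij[j] * (sr6^2 - 2 * sr6)
    if (identical(params$dielectric, "distance")) {
      elec <- elec + qq[j] / (r * r)
    } else {
      elec <- elec + qq[j] / (params$dielectric * r)
    }
  }
  cap <- params$cap
  steric <- pmin(pmax(steric, -cap), cap)
  steric[inside_core] <- cap
  elec <- pmin(pmax(elec, -cap), cap)
  structure(list(grid = grid, steric = steric, electrostatic = elec),
            class = "field_grid")
}

#' Assemble the descriptor matrix for a dataset
#'
#' Row i concatenates the steric and electrostatic fields of record i on the
#' shared grid; columns whose standard deviation across records falls below
#' `min_sigma` are dropped (classical CoMFA minimum-sigma filtering).
#'
#' @param records list of `complex_record`s in the common aligned frame.
#' @param grid a [grid_spec()] shared by all records.
#' @param params a [probe_params()].
#' @param min_sigma column standard-deviation threshold, kcal/mol.
#' @return list of class `descriptor_matrix` with `X` (kept columns only),
#'   `kept_mask` (logical over all columns), `column_info` (data.frame:
#'   point index, probe type), `y` (pK_D vector), `ids`, `ligand_ids`,
#'   `grid`, `params`, `min_sigma`.
#' @export
assemble_descriptor_matrix <- function(records, grid,
                                       params = probe_params(),
                                       min_sigma = 0.05) {
  if (length(records) == 0L) stop("empty dataset")
  rows <- lapply(records, function(r) {
    fg <- compute_probe_energies(r$structure, grid, params)
    c(fg$steric, fg$electrostatic)
  })
  X_full <- do.call(rbind, rows)
  n_pts <- prod(grid$dims)
  column_info <- data.frame(
    point = rep(seq_len(n_pts), 2L),
    probe = rep(c("steric", "electrostatic"), each = n_pts),
    stringsAsFactors = FALSE
  )
  sds <- apply(X_full, 2, sd)
  kept <- sds >= min_sigma
  structure(list(
    X = X_full[, kept, drop = FALSE],
    kept_mask = kept,
    column_info = column_info,
    y = vapply(records, function(r) r$pkd, numeric(1)),
    ids = vapply(records, function(r) r$structure$complex_id, character(1)),
    ligand_ids = vapply(records, function(r) r$ligand_id, character(1)),
    grid = grid, params = params, min_sigma = min_sigma
  ), class = "descriptor_matrix")
}

#' Field row for a single ligand under a descriptor layout
#'
#' Computes the concatenated steric/electrostatic field of one ligand on a
#' descriptor matrix's grid and applies its kept-column mask, giving a row
#' directly comparable to the training rows.
#'
#' @param descriptors a `descriptor_matrix`.
#' @param ligand a `complex_structure` (its ligand atoms are used).
#' @return numeric vector over kept columns.
#' @export
descriptor_row <- function(descriptors, ligand) {
  fg <- compute_probe_energies(ligand, descriptors$grid, descriptors$params)
  full <- c(fg$steric, fg$electrostatic)
  full[descriptors$kept_mask]
}

#' Export a field grid in OpenDX format
#'
#' Writes one scalar field (steric or electrostatic) as an OpenDX regular
#' grid for visual inspection in molecular viewers.
#'
#' @param fg a `field_grid`.
#' @param file output path.
#' @param which `"steric"` or `"electrostatic"`.
#' @return `file`, invisibly.
#' @export
write_opendx <- function(fg, file, which = c("steric", "electrostatic")) {
  which <- match.arg(which)
  g <- fg$grid
  vals <- fg[[which]]
  # OpenDX expects z fastest; our storage is x fastest
  arr <- array(vals, dim = g$dims)
  vals_dx <- as.vector(aperm(arr, c(3, 2, 1)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0 0", g$spacing),
    sprintf("delta 0 %.6f 0", g$spacing),
    sprintf("delta 0 0 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals_dx))
  ), con)
  writeLines(apply(matrix(c(vals_dx,
                            rep(NA, (3 - length(vals_dx) %% 3) %% 3)),
                          ncol = 3, byrow = TRUE), 1, function(r)
    paste(format(r[!is.na(r)], digits = 8), collapse = " ")), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(file)
}
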