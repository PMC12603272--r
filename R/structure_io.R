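# Default nucleic-acid backbone atom names, one set per nucleotide.
BACKBONE_ATOMS <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

#' Construct a ligand/DNA complex structure
#'
#' A `complex_structure` holds the atoms of one ligand/DNA-decamer complex in
#' a single coordinate frame, partitioned into receptor ("lock", the DNA
#' duplex) and ligand ("key") atoms.
#'
#' @param atoms data.frame with columns `element`, `name`, `chain`, `resno`,
#'   `resname`, `insert`, `x`, `y`, `z`, `charge`, `occ`, `b`, `is_ligand`.
#' @param complex_id identifier string.
#' @param source provenance string (e.g. a PDB id or "synthetic").
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(atoms, complex_id = "complex", source = "") {
  required <- c("element", "name", "chain", "resno", "resname", "insert",
                "x", "y", "z", "charge", "occ", "b", "is_ligand")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords)))
    stop("non-finite atom coordinates")
  if (!all(is.finite(atoms$charge)))
    stop("non-finite partial charges")
  structure(
    list(complex_id = complex_id, source = source,
         atoms = as.data.frame(atoms, stringsAsFactors = FALSE)),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure> %s (%s): %d receptor / %d ligand atoms\n",
              x$complex_id, x$source,
              sum(!x$atoms$is_ligand), sum(x$atoms$is_ligand)))
  invisible(x)
}

#' Atom coordinates of a complex structure
#'
#' @param x a `complex_structure`.
#' @param part `"all"`, `"receptor"` or `"ligand"`.
#' @return numeric matrix (n x 3) of coordinates in Angstrom.
#' @export
coords <- function(x, part = c("all", "receptor", "ligand")) {
  part <- match.arg(part)
  a <- x$atoms
  if (part == "receptor") a <- a[!a$is_ligand, , drop = FALSE]
  if (part == "ligand")   a <- a[a$is_ligand, , drop = FALSE]
  unname(as.matrix(a[, c("x", "y", "z")]))
}

# Validate ATOM/HETATM coordinate fields line by line; PDB is fixed-column so
# a bad float can be attributed to its line number before bio3d parses it.
check_pdb_coordinates <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      field <- substr(lines[i], cols[1], cols[2])
      if (is.na(suppressWarnings(as.numeric(field))))
        stop(sprintf("format error at line %d: unparseable coordinate field '%s'",
                     i, trimws(field)))
    }
  }
  invisible(idx)
}

#' Read a ligand/DNA complex from PDB-format input
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}) and partitions atoms into
#' ligand and receptor by residue name. Alternate locations other than blank
#' or "A" are dropped; insertion codes are retained. Coordinates are kept at
#' PDB precision (0.001 Angstrom).
#'
#' PDB carries no partial-charge column; with `charges_from = "occupancy"`
#' (or `"bfactor"`) the corresponding column is interpreted as the partial
#' charge in elementary-charge units, the convention used by
#' [write_complex()] and the synthetic fixture writer. The default
#' `"none"` assigns zero charges.
#'
#' @param x path to a PDB file, or a character vector of PDB lines.
#' @param ligand_resnames character vector of residue names identifying the
#'   ligand ("key"); everything else is receptor ("lock").
#' @param complex_id,source identifiers stored on the result.
#' @param charges_from one of `"none"`, `"occupancy"`, `"bfactor"`.
#' @return a [complex_structure()].
#' @export
read_complex <- function(x, ligand_resnames, complex_id = "complex",
                         source = "", charges_from = c("none", "occupancy",
                                                       "bfactor")) {
  charges_from <- match.arg(charges_from)
  if (length(ligand_resnames) == 0L)
    stop("ligand_resnames must be non-empty")
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    if (source == "") source <- basename(x)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    stop("no ATOM/HETATM records found")
  check_pdb_coordinates(lines)

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]

  element <- at$elesy
  bad <- is.na(element) | element == ""
  if (any(bad)) element[bad] <- element_from_name(at$elety[bad])
  chain <- ifelse(is.na(at$chain), "", at$chain)
  insert <- ifelse(is.na(at$insert), "", at$insert)
  occ <- ifelse(is.na(at$o), 0, at$o)
  bfac <- ifelse(is.na(at$b), 0, at$b)
  charge <- switch(charges_from, none = rep(0, nrow(at)),
                   occupancy = occ, bfactor = bfac)

  atoms <- data.frame(
    element = toupper(substr(element, 1, 1)) %p0%
      tolower(substr(element, 2, 2)),
    name = at$elety, chain = chain, resno = at$resno,
    resname = trimws(at$resid), insert = insert,
    x = at$x, y = at$y, z = at$z,
    charge = charge, occ = occ, b = bfac,
    is_ligand = trimws(at$resid) %in% ligand_resnames,
    stringsAsFactors = FALSE
  )
  if (!any(atoms$is_ligand))
    stop("empty ligand: no atoms matched residue name(s) ",
         paste(ligand_resnames, collapse = ", "))
  complex_structure(atoms, complex_id = complex_id, source = source)
}

`%p0%` <- function(a, b) paste0(a, b)

element_from_name <- function(name) {
  # first alphabetic character of the atom name; handles names like "C4'"
  sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name)
}

#' Write a complex structure to a PDB file
#'
#' Receptor atoms are written as ATOM records, ligand atoms as HETATM.
#' With `charges_to = "occupancy"` the occupancy column carries the partial
#' charges (see [read_complex()]).
#'
#' @param x a `complex_structure`.
#' @param file output path.
#' @param charges_to one of `"none"`, `"occupancy"`, `"bfactor"`.
#' @return `file`, invisibly.
#' @export
write_complex <- function(x, file,
                          charges_to = c("none", "occupancy", "bfactor")) {
  charges_to <- match.arg(charges_to)
  a <- x$atoms
  o <- a$occ
  b <- a$b
  if (charges_to == "occupancy") o <- a$charge
  if (charges_to == "bfactor") b <- a$charge
  bio3d::write.pdb(
    file = file,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$is_ligand, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resname,
    chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$insert == "", "", a$insert),
    elety = a$name, o = o, b = b, elesy = toupper(a$element)
  )
  invisible(file)
}

#' Split a complex into receptor ("lock") and ligand ("key") parts
#'
#' Coordinates are unchanged: both parts stay in the complex's frame, so
#' superposed complexes yield superposed ligands.
#'
#' @param x a `complex_structure`.
#' @return list with elements `receptor` and `ligand`, both
#'   `complex_structure` objects.
#' @export
split_lock_key <- function(x) {
  stopifnot(inherits(x, "complex_structure"))
  rec <- x$atoms[!x$atoms$is_ligand, , drop = FALSE]
  lig <- x$atoms[x$atoms$is_ligand, , drop = FALSE]
  if (nrow(lig) == 0L) stop("empty ligand")
  if (nrow(rec) == 0L) stop("empty receptor")
  list(
    receptor = complex_structure(rec, complex_id = x$complex_id,
                                 source = x$source),
    ligand = complex_structure(lig, complex_id = x$complex_id,
                               source = x$source)
  )
}

#' Merge receptor and ligand parts back into one complex
#'
#' Inverse of [split_lock_key()]; the atom multiset is conserved.
#'
#' @param receptor,ligand `complex_structure` objects sharing a frame.
#' @return a `complex_structure`.
#' @export
merge_lock_key <- function(receptor, ligand) {
  atoms <- rbind(receptor$atoms, ligand$atoms)
  complex_structure(atoms, complex_id = receptor$complex_id,
                    source = receptor$source)
}

#' Rigid-body superposition onto a reference via the DNA backbone
#'
#' Least-squares (Kabsch) superposition of `mobile` onto `reference` using
#' receptor backbone atoms matched by (chain, residue number, atom name).
#' Reflections are rejected: the returned rotation is always proper
#' (determinant +1). The transform maps a coordinate column vector v to
#' `rotation \%*\% v + translation`.
#'
#' @param mobile,reference `complex_structure` objects.
#' @param backbone_names atom names defining the backbone; default
#'   P, O5', C5', C4', C3', O3'.
#' @return list of class `superposition` with `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Angstrom, over matched atoms after
#'   the transform) and `n_matched`.
#' @export
superpose_backbone <- function(mobile, reference,
                               backbone_names = BACKBONE_ATOMS) {
  key <- function(a) paste(a$chain, a$resno, a$insert, a$name, sep = "|")
  bb <- function(x) {
    a <- x$atoms[!x$atoms$is_ligand & x$atoms$name %in% backbone_names, ,
                 drop = FALSE]
    a
  }
  am <- bb(mobile); ar <- bb(reference)
  km <- key(am); kr <- key(ar)
  common <- intersect(km, kr)
  if (length(common) < 3L)
    stop("fewer than 3 matched backbone atoms (", length(common), ")")
  pm <- as.matrix(am[match(common, km), c("x", "y", "z")])
  pr <- as.matrix(ar[match(common, kr), c("x", "y", "z")])
  kb <- kabsch(pm, pr)
  fitted <- sweep(pm %*% t(kb$rotation), 2, kb$translation, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - pr)^2)))
  structure(list(rotation = kb$rotation, translation = kb$translation,
                 rmsd = rmsd, n_matched = length(common)),
            class = "superposition")
}

# Kabsch: proper rotation R and translation t minimizing ||R p_i + t - q_i||.
# p, q are n x 3 matrices of paired coordinates.
kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  sv <- svd(crossprod(pc, qc))
  # rank < 2 means the points are collinear (or coincident): the in-plane
  # rotation is undetermined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set: superposition is undetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, translation = as.vector(cq - rot %*% cp))
}

#' Apply a rigid superposition to a whole complex
#'
#' Receptor and ligand atoms are transformed with the same rigid motion.
#'
#' @param x a `complex_structure`.
#' @param sp a `superposition` from [superpose_backbone()].
#' @return the transformed `complex_structure`.
#' @export
apply_superposition <- function(x, sp) {
  xyz <- coords(x)
  new_xyz <- sweep(xyz %*% t(sp$rotation), 2, sp$translation, `+`)
  x$atoms$x <- new_xyz[, 1]; x$atoms$y <- new_xyz[, 2]
  x$atoms$z <- new_xyz[, 3]
  x
}

#' Structure preparation hook
#'
#' Inputs are assumed already protonated and energy minimized; this no-op
#' hook is the seam where a force-field preparation step can be plugged in.
#'
#' @param x a `complex_structure`.
#' @param fun a function `complex_structure -> complex_structure`.
#' @return `fun(x)`.
#' @export
prepare_complex <- function(x, fun = identity) fun(x)

#' Construct a complex record (structure + measured affinity)
#'
#' @param structure a `complex_structure` in the common aligned frame.
#' @param kd dissociation constant in mol/L; must be positive.
#' @param ligand_id ligand identifier; the same ligand may appear in several
#'   records (bound to different DNA sequences or in different
#'   conformations).
#' @return object of class `complex_record` with `pkd = -log10(kd)`.
#' @export
complex_record <- function(structure, kd, ligand_id) {
  stopifnot(inherits(structure, "complex_structure"))
  if (!is.finite(kd) || kd <= 0) stop("kd must be positive and finite")
  structure(list(structure = structure, kd = kd, pkd = -log10(kd),
                 ligand_id = as.character(ligand_id)),
            class = "complex_record")
}

#' @export
print.complex_record <- function(x, ...) {
  cat(sprintf("<complex_record> %s ligand=%s pK_D=%.3f (K_D=%.3g M)\n",
              x$structure$complex_id, x$ligand_id, x$pkd, x$kd))
  invisible(x)
}

#' Read a dataset manifest
#'
#' The manifest CSV lists one complex per row with columns `complex_id`,
#' `pdb_id`, `ligand_id`, `kd_molar`.
#'
#' @param file path to the CSV.
#' @return data.frame with the four columns, `kd_molar` numeric.
#' @export
read_manifest <- function(file) {
  if (!file.exists(file)) stop("manifest not found: ", file)
  m <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("complex_id", "pdb_id", "ligand_id", "kd_molar")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0L)
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(m$kd_molar) | m$kd_molar <= 0))
    stop("kd_molar must be positive")
  m
}

#' Align a set of complexes onto a common frame
#'
#' Every complex is superposed onto the reference via the DNA backbone; the
#' reference is the first record unless `reference_id` names another one.
#'
#' @param records list of `complex_record`s.
#' @param reference_id complex_id of the alignment reference (default: the
#'   first record).
#' @param backbone_names see [superpose_backbone()].
#' @return list with `records` (aligned) and `alignment_rmsd` (named vector,
#'   Angstrom).
#' @export
align_dataset <- function(records, reference_id = NULL,
                          backbone_names = BACKBONE_ATOMS) {
  stopifnot(length(records) >= 1L)
  ids <- vapply(records, function(r) r$structure$complex_id, character(1))
  ref_idx <- if (is.null(reference_id)) 1L else match(reference_id, ids)
  if (is.na(ref_idx)) stop("reference_id not found: ", reference_id)
  ref <- records[[ref_idx]]$structure
  rmsds <- numeric(length(records))
  for (i in seq_along(records)) {
    sp <- superpose_backbone(records[[i]]$structure, ref,
                             backbone_names = backbone_names)
    records[[i]]$structure <- apply_superposition(records[[i]]$structure, sp)
    rmsds[i] <- sp$rmsd
  }
  names(rmsds) <- ids
  list(records = records, alignment_rmsd = rmsds)
}
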