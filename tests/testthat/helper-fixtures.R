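# Shared fixtures and independent oracles used across test files.

# Minimal 3-atom PDB: two DNA backbone atoms + one ligand atom.
tiny_pdb_lines <- function() {
  c(
    "ATOM      1  P    DA A   1       1.000   2.000   3.000  1.00  0.00           P",
    "ATOM      2  C4'  DA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "HETATM    3  C1  LIG X   1       0.000   0.000   0.000  0.25  0.00           C",
    "END"
  )
}

# Small aligned structure with a non-degenerate backbone for superposition
# tests: 6 backbone atoms on a helix-ish path + 2 ligand atoms.
toy_complex <- function(id = "toy") {
  bb <- data.frame(
    element = c("P", "O", "C", "C", "C", "O"),
    name = c("P", "O5'", "C5'", "C4'", "C3'", "O3'"),
    chain = "A", resno = rep(1:2, each = 3),
    resname = "DA", insert = "",
    x = c(0, 1, 2, 3.5, 4, 5.2), y = c(0, 1.2, 0.3, 1.8, 2.5, 2.1),
    z = c(0, 0.5, 1.4, 2.2, 3.3, 4.1),
    charge = 0, occ = 1, b = 0, is_ligand = FALSE,
    stringsAsFactors = FALSE
  )
  lig <- data.frame(
    element = c("C", "N"), name = c("C1", "N1"), chain = "X",
    resno = 1L, resname = "LIG", insert = "",
    x = c(2, 2.8), y = c(-1, -1.5), z = c(1, 2),
    charge = c(0.1, -0.2), occ = 0, b = 0, is_ligand = TRUE,
    stringsAsFactors = FALSE
  )
  complex_structure(rbind(bb, lig), complex_id = id, source = "fixture")
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rigidly_move <- function(cs, rot, shift) {
  xyz <- coords(cs)
  new <- sweep(xyz %*% t(rot), 2, shift, `+`)
  cs$atoms$x <- new[, 1]; cs$atoms$y <- new[, 2]; cs$atoms$z <- new[, 3]
  cs
}

# Quaternion -> rotation matrix; used by the brute-force superposition oracle.
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Brute-force least-RMSD superposition over rotations parameterized by
# quaternions (many random restarts + Nelder-Mead), independent of the
# closed-form solver it checks.
brute_force_superpose_rmsd <- function(p, q, n_starts = 40) {
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  obj <- function(quat) {
    R <- quat_to_rot(quat)
    sqrt(mean(rowSums((pc %*% t(R) - qc)^2)))
  }
  best <- Inf
  set.seed(7)
  for (s in seq_len(n_starts)) {
    res <- optim(rnorm(4), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, res$value)
  }
  best
}

# Exhaustive element-preserving permutation minimum RMSD (<= 8 atoms).
brute_force_symmetry_rmsd <- function(pe, pc, re, rc) {
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  els <- unique(pe)
  per_el <- lapply(els, function(el) perms_of(which(re == el)))
  idx_p <- lapply(els, function(el) which(pe == el))
  combos <- expand.grid(lapply(per_el, seq_along))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    perm <- integer(length(pe))
    for (k in seq_along(els))
      perm[idx_p[[k]]] <- per_el[[k]][[combos[r, k]]]
    best <- min(best, sqrt(mean(rowSums((pc - rc[perm, , drop = FALSE])^2))))
  }
  best
}

# Literal leave-one-out loop, written independently of loo_validate.
brute_force_loo <- function(X, y, ncomp) {
  n <- nrow(X)
  preds <- vapply(seq_len(n), function(i) {
    m <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp)
    predict(m, X[i, ])
  }, numeric(1))
  press <- sum((y - preds)^2)
  list(q2 = 1 - press / sum((y - mean(y))^2), sdep = sqrt(press / n))
}

# Low-rank regression instance where y is exactly linear in X.
lowrank_instance <- function(n = 20, latent = 3, p = 40, seed = 11) {
  set.seed(seed)
  Z <- matrix(rnorm(n * latent), n, latent)
  A <- matrix(rnorm(latent * p), latent, p)
  list(X = Z %*% A, y = drop(Z %*% seq_len(latent)))
}

paper_titration <- function(seed = 1, noise_cv = 0.02, kd = 1e-7) {
  simulate_titration(1e-5, seq(0, 1e-5, by = 5e-7), kd,
                     fmax = 1000, f0 = 10, noise_cv = noise_cv, seed = seed)
}
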