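---
title: "Methods: field-based affinity modeling of DNA minor-groove binders"
author: "groovebind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field-based affinity modeling of DNA minor-groove binders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovebind)
```

## The problem

Crescent-shaped small molecules such as Hoechst 33258 bind the minor groove
of B-form double-stranded DNA. Predicting the dissociation constant K~D~ of
a new candidate groove binder from structure is the core task this package
addresses. The workflow is the classical field-based 3D-QSAR one:

1. assemble a panel of ligand/DNA-decamer complexes with measured K~D~,
   superposed on a common frame through their DNA backbones;
2. sample steric (Lennard-Jones) and electrostatic (Coulomb) probe
   energies for each aligned ligand on a shared 3D grid (CoMFA fields);
3. regress pK~D~ = −log10(K~D~) on those fields by partial least squares
   (PLS), validating internally (leave-one-out q²) and externally
   (q²~ext~, SDEP~ext~ on held-out ligands);
4. use the fitted models as an *external scoring function*: compute the
   field row of a docked pose of a new ligand and predict its pK~D~,
   averaging across models and poses.

Alongside the modeling chain, the package implements the supporting assay
mathematics: the exact 1:1 tight-binding isotherm and the saturation
stoichiometry of a photoluminescence titration, fluorescence polarization,
and the cell doubling-time formula.

## Structures, alignment and the lock/key convention

Complexes are read from PDB (`read_complex()`); atoms are partitioned into
receptor ("lock", the DNA duplex) and ligand ("key") by residue name, and
alternate locations other than blank/"A" are dropped. Superposition
(`superpose_backbone()`) is a closed-form least-squares rigid fit (SVD,
reflections rejected) over backbone atoms matched by chain, residue number
and atom name. The backbone atom set defaults to P, O5', C5', C4', C3',
O3' — the standard nucleic-acid backbone; it is configurable. The first
record of a dataset is the alignment reference unless another is named;
nothing in the method depends on which frame is chosen, only that it is
shared. Hydrogen addition and energy minimization are deliberately *not*
implemented: inputs are assumed prepared, and `prepare_complex()` is a
no-op hook where a force-field step can be plugged in.

PDB has no partial-charge column, so the package adopts the PQR-like
convention of carrying charges in the occupancy column
(`charges_from = "occupancy"`); the synthetic writer uses the same
convention, which bounds on-disk charge precision at 0.01 e.

## Molecular interaction fields

Fields are evaluated on a rectilinear grid (default spacing 2 Å, padding
4 Å around the ligand ensemble) with an sp³-carbon probe (Lennard-Jones
r~min~ 1.7 Å, well depth 0.107 kcal/mol) carrying +1 e. At each point,

- electrostatic energy: Σ~atoms~ 332.06 · q~probe~ q~i~ / (ε(r) · r), in
  kcal/mol, with a distance-dependent dielectric ε(r) = r by default;
- steric energy: Lennard-Jones 6-12 with Lorentz–Berthelot combination
  (r~min~ additive, well depths by geometric mean).

Both fields are clamped to ±30 kcal/mol and points inside an atom's core
get the positive cap — the conventional CoMFA treatment that keeps the
regression from being dominated by near-singular contacts. Columns whose
standard deviation across the panel falls below `min_sigma` (default
0.05 kcal/mol) are removed. All of these are defaults of the classical
CoMFA formulation, declared rather than inferred, and every one is a
function argument.

Note one consequence of the 1/r (or 1/r²) Coulomb form: the electrostatic
field of a unit charge is *not* negligible even 50 Å away. Far-field decay
statements in the tests therefore use the distance-dependent dielectric
and realistic partial charges.

## PLS regression and the three protocols

PLS is fit by NIPALS on mean-centered X and y (column scaling available
but off by default: CoMFA fields share units). The implementation keeps
the per-component coefficient path, so leave-one-out validation refits
each fold once and reads off predictions for every component count.
Component choice maximizes LOO q², with ties (within 1e-10) broken toward
fewer components. q² = 1 − PRESS/SS~tot~ with SS~tot~ about the full-set
mean; externally, q²~ext~ uses the training-set mean in the denominator
and SDEP~ext~ = √(PRESS~ext~/n~test~) — the standard QSAR conventions.

Three model protocols mirror common practice on a small panel:

- **Model 1** trains on every record and reports training r² plus LOO
  q²/SDEP.
- **Model 2** fits on a seeded 80/20 split and reports q²~ext~/SDEP~ext~
  on the held-out 20%. The split is *grouped by ligand identity*: such
  panels typically contain the same ligand in more than one complex, and
  splitting within a ligand would leak information into the test set.
- **Model 3** refits on the full panel with the component count selected
  in Model 2.

## Pose evaluation and rescoring

Docked poses are compared to the crystal ligand by symmetry-corrected
RMSD in the fixed receptor frame (no refitting of a rigid transform — the
docking convention). Chemical equivalence is handled by optimal assignment
(Hungarian algorithm) on squared distances within each element class;
because the objective separates over elements, the per-class optimum is
the global optimum over element-preserving permutations. Full
graph-automorphism enumeration is retained only as a test oracle for
small instances. Redocking accuracy is the fraction of poses within a
threshold, default 2 Å — the field-standard success criterion.

Rescoring computes a pose's field row under the training descriptor
layout (same grid, probe and kept-column mask) and applies each model;
the reported affinity is the unweighted arithmetic mean of pK~D~ over all
(model, pose) pairs, converted to K~D~ in nM as 10^(−pK~D~)·10⁹. Docking
itself is out of scope: the package consumes poses, it does not generate
them. Whether to rescore the best-scored or all poses is the caller's
choice; functions accept any pose list.

## Binding-assay mathematics

Because the K~D~ values of interest (tens to hundreds of nM) sit far
below the working ligand concentration (10 µM), ligand depletion is
material and the exact 1:1 quadratic isotherm is used throughout:

  [LD] = ((L + D + K~d~) − √((L + D + K~d~)² − 4LD)) / 2.

`fit_titration()` fits (K~d~, f~max~, f₀) by Levenberg–Marquardt with
K~d~ on a log scale, and reports the **saturation stoichiometry** as the
intersection of the initial-rise line (fit on points with fitted bound
fraction ≤ 0.5) with the fitted plateau f₀ + f~max~ — the classical
equivalence-point construction. A free two-segment least-squares knee was
evaluated and rejected: a titration that stops at the equivalence point
(dsDNA titrated 0–10 µM against 10 µM ligand) leaves the second segment
essentially unsupported, and the knee estimate collapses (observed range
0.5–0.94 across noise seeds, against 0.97–1.07 for the equivalence-point
construction).

A related identifiability caveat: in the tight-binding regime the
titration determines the *stoichiometry* precisely but the *constant*
poorly — K~D~ enters only through the slight rounding of the knee, so at
2% multiplicative intensity noise the relative error of the fitted K~D~
is of order 20% even for an extended titration. The tests therefore
assert K~D~ recovery under noise in a regime where it is identifiable
(K~D~ ~ 2 µM) and exactly (to 1e-6) at zero noise.

Fluorescence polarization is FP = 1000(S − G·P)/(S + G·P) in mP, and the
doubling time is 24·ln 2 / ln(N₇₂/N₄₈) hours, with a shrinking-population
flag when N₇₂ < N₄₈.

## The synthetic-data generator

All inputs the pipeline consumes can be generated
(`make_synthetic_complexes()`, `make_pose_set()`,
`make_titration_panel()`), so every stage is testable without downloads.
The complex generator emulates the study design: ~27 complexes in one
aligned frame, pK~D~ in [5, 9] (bracketing a predicted 6.54–7.59 window),
pK~D~ linear in field-grid columns plus Gaussian noise (default SD
0.15 pK~D~), and a few records sharing a ligand identity as real
minor-groove panels do.

Its key design choice: ligands share a *scaffold* of six fixed sites
(C/N/O) and vary only their partial charges, drawn uniformly in
[−0.12, 0.12] e. Sites sit mid-cell on the truth grid with pairwise
separation ≥ 4 Å, which keeps every field value strictly inside the
±30 kcal/mol clamp; the electrostatic descriptor block is then *exactly*
linear in the charges and the descriptor matrix has rank six. That makes
the noiseless pK~D~ exactly recoverable by PLS — training r², LOO q² and
external q²~ext~ all equal 1 to machine precision at zero noise — which
is the property the validation tests and the end-to-end rescoring check
rely on. With noise SD 0.15 the observed q²~ext~ is checked against the
empirical 95% band of 200 regenerated panels.

What the generator does *not* emulate: real DNA stereochemistry (the
decamer is a schematic helix with correct backbone atom names, chains and
numbering), conformational variety between duplicated ligand records
(they share coordinates exactly), bond topology, and any relationship
between receptor sequence and affinity. Passing tests therefore
demonstrate the correctness of the machinery — alignment, fields, PLS,
validation protocol, rescoring — not predictive performance on
crystallographic data, which additionally depends on structure
preparation and docking quality.

Pose sets are built by rigid translation along random directions: a
uniform translation of magnitude d has RMSD exactly d, so target RMSDs
are hit to machine precision. Titration panels default to the assay
design above (10 µM ligand, 0–10 µM dsDNA in 0.5 µM steps, 2% noise).

## Numerical choices and degenerate inputs

- Superposition requires ≥ 3 matched backbone atoms and rejects collinear
  point sets (second singular value below 1e-8 of the first), where the
  in-plane rotation is undetermined.
- NIPALS stops early if X is deflated to numerical noise (weight or score
  norm < 1e-12); requesting more components than the data support yields
  the supported number.
- Component-selection ties use a 1e-10 q² tolerance, resolved toward
  fewer components.
- `bound_complex()` clips tiny negative discriminants to zero and clamps
  the root into [0, min(L, D)].
- Degenerate inputs error early with the offending quantity named:
  constant response vectors, constant correlation inputs, empty RMSD
  lists, equal cell counts (undefined doubling time), non-increasing DNA
  series.

## Problem sizes used by the tests

The test suite and acceptance script run entirely on generated data:
27-complex panels on a 9×9×9 grid (1458 descriptor columns before
filtering), 21-point titrations, pose sets of a handful of poses, and a
200-panel rerun for the q²~ext~ band. These sizes make every check a
from-scratch computation while keeping the whole suite under a couple of
minutes on one core.

## Worked example

```{r example, eval = FALSE}
ds <- make_synthetic_complexes(n = 27, noise_sd = 0.15, seed = 3)
dm <- assemble_descriptor_matrix(ds$records, ds$truth$grid)
rp <- run_protocols(dm, split_seed = 7)
rp

ho <- synthetic_holdout(ds$truth, seed = 42)
lig <- ho$structure$atoms[ho$structure$atoms$is_ligand, ]
rescore_pose(lapply(rp, function(r) r$model), pose(lig), dm)

fit_titration(make_titration_panel(100e-9, seed = 1)[[1]])
```

## Known limitations

- No hydrophobic or hydrogen-bond probes (CoMSIA-style fields), no
  charge assignment (charges are taken from input), no conformer
  generation and no docking engine integration — by design, the package
  consumes prepared structures and pose files.
- The synthetic panel's exact linear structure is an idealization;
  real field/affinity relationships are noisy and nonlinear, and external
  q² on crystallographic panels will be far below the synthetic values.
- The titration stoichiometry estimator assumes a single 1:1 binding
  mode; cooperative or multi-site binding will shift the breakpoint.
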