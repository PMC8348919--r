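---
title: "Methods: field-based QSAR, validation statistics, and the screening funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field-based QSAR, validation statistics, and the screening funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xoiqsar)
```

# What this package computes

`xoiqsar` re-implements, as tested R code, the in-silico chain used to
study 2-substituted 6-oxo-1,6-dihydropyrimidine-5-carboxylic acid (ODC)
inhibitors of xanthine oxidase (XO), the enzyme whose over-activity drives
hyperuricemia and gout. The chain has five stages, each a package module:

1. **Compound dataset** — a packaged table of 46 ODC inhibitors plus the
   febuxostat reference: IC50 (uM), actual and model-predicted pIC50,
   training/test split (35/11), and the 12-compound pharmacophore set.
2. **Conformers and alignment** — one seeded low-energy 3D conformer per
   molecule with Gasteiger charges, superposed onto a shared core by
   least-squares (Kabsch) rigid fitting.
3. **Field engine** — steric (Lennard-Jones) and electrostatic (Coulomb)
   probe fields and Gaussian similarity-index fields sampled on a shared
   lattice: the CoMFA/CoMSIA descriptor matrices.
4. **PLS QSAR + validation** — NIPALS partial least squares with
   leave-one-out cross-validation, component selection, field
   contributions and StDev*Coeff contour extraction; the full external
   validation suite (RMSE, through-origin regressions, the rm2 family,
   predictive r2, and the acceptability threshold battery).
5. **Screening and post-MD analytics** — pharmacophore matching with a
   0-100 compliance score, decoy-set enrichment (EF, Guner-Henry GH), the
   staged ADME funnel, MM-PBSA component aggregation, and trajectory
   metrics (Kabsch RMSD, RMSF, radius of gyration, hydrogen-bond counts).

A seeded synthetic-data module generates inputs with the statistical
structure each stage assumes, so the whole pipeline is testable without
proprietary modelling software.

# Activity units

pIC50 is defined on molar concentration: for IC50 in uM,
`pIC50 = 6 - log10(IC50)`. This is the only convention consistent with
the packaged table (0.0920 uM maps to 7.0362), and it is verified for all
47 rows at load time. Residuals are held signed internally
(predicted - actual); magnitudes are formed only for display.

# Fields and their parameters

All lattice parameters are package defaults chosen from common practice
for this method family, since no single canonical set exists:

* **Lattice**: spacing 2.0 Å, margin 4.0 Å around the union bounding box
  of the aligned set. The box grows monotonically with the molecule set,
  so adding a molecule inside the hull leaves the grid unchanged.
* **Probe**: an sp3 carbon with +1.0 e charge. Element 6-12 parameters
  (minimum-energy radius, well depth) come from a bundled table in the
  style of the Tripos force field.
* **Steric field**: `eps_ij * ((R_ij/r)^12 - 2 (R_ij/r)^6)` summed over
  atoms, truncated to +/-30 kcal/mol. The positive cap marks the steric
  clash region.
* **Electrostatic field**: `332.06 q_p q_a / r^2` (kcal/mol), i.e. the
  Coulomb potential with distance-dependent dielectric eps = r. Values at
  a compound's clashed grid points are replaced by the column mean over
  non-clashed compounds during matrix assembly — a clash region carries
  no meaningful electrostatics, and column-mean imputation leaves the
  column's centered contribution to the regression neutral.
* **Similarity indices**: `-sum_i w_p w_i exp(-alpha r^2)` with
  attenuation alpha = 0.3 1/Å^2 (the method's published default) and
  probe weight +1. Property weights per atom: vdW radius cubed (steric),
  Gasteiger charge (electrostatic), Crippen atomic logP contribution
  (hydrophobic), donor/acceptor indicator (H-bond fields). The Gaussian
  form is bounded everywhere, including at atom centers.
* **Column filter**: descriptor columns with standard deviation below a
  user threshold are dropped and recorded; the filter is idempotent.

# Conformers, charges, and alignment

3D embedding must be bitwise-deterministic for a given (SMILES, seed), so
it is delegated to RDKit's seeded ETKDG distance-geometry embedding
followed by MMFF minimization, via a bundled helper script run through
the system `python`. The same helper supplies Gasteiger charges, Crippen
atomic hydrophobicity, rule-based donor/acceptor flags, ring membership
and SMARTS substructure matches. One conformer per molecule is used — the
modelling protocol this emulates works from a single minimized pose.

Alignment matches a core SMARTS in molecule and template and applies the
Kabsch least-squares rigid transform of the matched atoms to the whole
molecule. When a core matches in several ways (symmetric rings), the
pairing with the smallest core RMSD wins, with ties resolved by match
enumeration order; the original protocol's "manual adjustment" is not
reproducible, so this deterministic rule replaces it.

# PLS and cross-validation

The regression is classical NIPALS PLS1 on mean-centered data without
column autoscaling (the molecular-field convention): components are
extracted from the X'y covariance direction with deflation, stopping
early (and reporting it) when the residual covariance collapses on
rank-deficient input. Derived statistics follow the chemometrics
conventions: `SEE = sqrt(SS_res / (n - c - 1))` and
`F = (R2/c) / ((1 - R2)/(n - c - 1))` with `c` extracted components.

`q2 = 1 - PRESS/SS_total` uses single-left-out refits in row order;
SS_total is taken about the full training-set mean (not the per-fold
means) — the more common convention, fixed here and used consistently.
The optimal component count is the smallest whose q2 lies within 5%
(relative) of the scan maximum over 1..max — a declared, configurable
parsimony rule; the software this emulates does not publish its rule, so
component counts are not compared against the reference models'.

Field contributions are shares of `sum |coefficient * column sd|` per
field block — the same StDev*Coeff product whose upper/lower percentiles
(defaults 80/20) define favored/disfavored contour points.

# External validation

For test-set actual (y) vs predicted (yhat) activities the report
computes RMSE, squared Pearson r2, and both through-origin regressions.
The orientation convention is concrete: `k = sum(y yhat)/sum(yhat^2)`
with `r0^2 = 1 - sum((y - k yhat)^2)/sum((y - mean y)^2)`, and the primed
pair with roles swapped. Two opposite labeling conventions circulate for
these statistics; the one implemented is the one that reproduces the
packaged reference table from its own activity data at printed precision,
which the test suite asserts. The rm2 family is
`rm2 = r2 (1 - sqrt(r2 - r0^2))` per orientation, with the radicand
clamped at 0 (and a warning) in the degenerate `r0^2 > r2` case the
formula is undefined for. `r_pred^2` is
`1 - sum((yhat - y)^2) / sum((y - mean(y_train))^2)`.

The threshold battery evaluates: q2 > 0.5, model R2 > 0.8,
(r2 - r0^2)/r2 < 0.1 for at least one orientation, 0.85 <= k (or k') <=
1.15, delta rm2 < 0.2, mean rm2 > 0.5, r_pred^2 > 0.6.

# Pharmacophore matching and enrichment

A hypothesis is a set of typed feature spheres (acceptor, donor,
hydrophobe, negative center; the reference model has 3/2/2/1). Molecule
feature points are typed by rule: donor/acceptor atoms, all-carbon ring
centroids as hydrophobes, carboxyl(ate) centroids and formally negative
atoms as negative centers. Matching is greedy one-to-one in hypothesis
row order within each feature's radius, and the compliance score is
`100 (matched/total) exp(-msd / mean(radius^2))` — a declared surrogate
on the 0-100 scale, not a reimplementation of any proprietary fitness
function; the funnel's stage-1 threshold applies to this surrogate.

Enrichment uses `EF = (Ha/Ht)/(A/D)` and
`GH = (Ha (3A + Ht)/(4 Ht A)) (1 - (Ht - Ha)/(D - A))`. Besides the
stated invariants `Ha <= Ht <= D`, `Ha <= A <= D`, the implementation
enforces `Ht - Ha <= D - A` (a hit list cannot contain more decoys than
exist); under these, GH lies in [0, 1], which a property test sweeps.

# The screening funnel

Three ordered stages: pharmacophore score > 35; docking score > 10 (an
input column — docking itself is out of scope); then the ADME gate:
150 < MW < 500 g/mol, 20 < TPSA < 130 Å^2, high GI absorption, no
blood-brain-barrier permeation, SA score < 4.5, zero Lipinski violations,
and at most one of the five CYP450 inhibition flags. The CYP rule
operationalizes "low CYP inhibition" as the loosest threshold under which
all four reference hits pass (each carries exactly one flag) while the
febuxostat reference, with three flags, fails; it is configurable.

Numeric bounds are compared at the precision the criterion is written
with (a half-unit tolerance: "130" admits < 130.5, "4.5" admits < 4.55).
This is a deliberate design choice: the reference hit list contains a
compound with TPSA 130.3 that its own screen accepted, so the strict
reading of "< 130" is inconsistent with the screen that produced the
data. `funnel_config(precision_tol = FALSE)` restores strict printed
inequalities. GI/BBB/CYP/SA are consumed as input columns; the external
predictors that produce them are out of scope.

# Post-MD metrics

Energies are kJ/mol; trajectories are nm internally (Å inputs are
rescaled on read with an explicit factor). Binding free energy is the
end-point difference `G_complex - G_free_protein - G_free_ligand`, and
the MM-PBSA decomposition sums van der Waals, electrostatic,
polar-solvation and surface-area terms; the packaged six-complex table
satisfies the sum identity within 0.01 kJ/mol.

RMSD uses Kabsch superposition with proper-rotation (determinant)
correction. RMSF superposes frames on the time-average structure (a
provisional first-frame alignment, then re-alignment to the resulting
mean — two passes, deterministic), takes per-atom RMS deviations about
the final mean, averages within residues, and flags residues above
0.35 nm (configurable). The superposition selection mask matters: fitting
on all atoms lets a mobile region drag the frame and redistributes
apparent fluctuation, so fluctuation analyses should mask to the stable
region. Radius of gyration is mass-weighted, with standard atomic masses
derived from element symbols when masses are absent. Hydrogen bonds are
counted geometrically: donor-acceptor distance <= 0.35 nm and
donor-H-acceptor angle >= 120 degrees, the common MD-analysis defaults
(the emulated protocol names none).

# Synthetic data: what it emulates, and what it does not

* `make_field_dataset` draws descriptors from a low-rank factor model
  (plus a small full-rank perturbation) and plants a unit-norm
  coefficient vector in the loading span, with homoscedastic Gaussian
  activity noise; defaults (n = 40 compounds, 50 columns, 3 factors,
  sigma = 0.1 — the magnitude of the reference models' residuals) define
  the recovery test conditions. It emulates the collinear,
  low-effective-rank structure of lattice fields, not their spatial
  smoothness or chemistry.
* `make_decoy_screen` draws Bernoulli hit-list membership for A = 35
  actives among D = 6269 database compounds (the reference decoy-screen
  shape) at stated retrieval rates. It emulates counts only; no decoy
  structures are generated.
* `make_trajectory` applies a known per-frame rigid motion plus isotropic
  Gaussian jitter to a random reference structure and records the
  expected post-superposition RMSD, `noise * sqrt(3 (1 - 1/n))`. It has
  no bonded structure, so RMSF/H-bond behaviour on it probes the
  estimators, not protein physics.

Passing tests on these generators show the statistics and geometry are
computed correctly under the assumed structure; they do not show that
real field matrices satisfy that structure, and the reference models'
internal q2/R2 are not reproducible here because the original
conformations and grid are unpublished.

# Numerical choices and degenerate inputs

* NIPALS deflation stops at relative covariance norm 1e-12; PLS1 needs no
  inner iteration loop.
* The rm2 radicand clamp (with warning) handles `r0^2 > r2`.
* Empty hit lists return EF = GH = 0 with a warning rather than NaN.
* The steric cap bounds both tails at +/-30 kcal/mol, so descriptor
  values are finite by construction; similarity indices are finite
  everywhere by the Gaussian form.
* Funnel rows missing a value required by a stage are rejected at that
  stage with a recorded reason, never silently passed.
* Problem sizes in the test-suite and analysis scripts (12-molecule
  synthetic series, 40 x 50 recovery problems, 500-atom / 50-frame
  trajectories, 200-candidate funnels) were chosen as the smallest sizes
  at which the statistical properties under test are stable.

# Known limitations

* ODC structures are not reconstructed from substituent labels; the
  conformer-to-PLS chain is exercised on synthetic series and the
  febuxostat reference, and the packaged activity tables carry the
  numerical reproduction work.
* The pharmacophore hypothesis generator (a genetic-algorithm alignment
  in the original toolchain), docking, the external ADME predictors, and
  the MD engine itself are out of scope; their outputs are consumed as
  packaged inputs.
* Printed contour maps are not reproduced; the contour module exposes the
  underlying StDev*Coeff point sets and an OpenDX export instead.
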