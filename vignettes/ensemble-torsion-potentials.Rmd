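---
title: "From scored structural ensembles to MD torsion potentials"
author: "EnsemblePEF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From scored structural ensembles to MD torsion potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EnsemblePEF)
```

## The problem

Chemical-shift-based structure generators such as CS-Rosetta turn NMR
backbone shifts into thousands of scored all-atom models, but they cannot
carry cofactors, ions or ligands through the calculation. A way to keep
the experimentally grounded backbone information while completing the
model in a molecular dynamics engine is to convert the ensemble's
per-residue phi/psi dihedral statistics into torsion potentials that
*replace* the force field's own backbone proper-dihedral terms. The MD
run then samples conformations compatible with the measured shifts while
the re-inserted cofactors interact freely with the protein.

EnsemblePEF implements that conversion: ensemble in, tabulated dihedral
potentials plus a topology patch out, with the analytics needed to compare
ensembles before and after refinement.

## The model

For residue $i$ and angle kind $\phi$ or $\psi$, the ensemble provides
samples $\alpha_{ij}$ (model $j = 1 \dots N$). The density is a circular
kernel density estimate built from a power-raised cosine kernel

$$K(\alpha, \alpha_{ij}) = \cos^k\!\left(\Delta(\alpha, \alpha_{ij})
\cdot \frac{\pi}{360^\circ}\right),$$

where $\Delta$ is the circular distance, $|\alpha - \alpha_{ij}|$ or
$360^\circ$ minus it, always in $[0^\circ, 180^\circ]$. The kernel equals
1 at zero distance, 0 at the antipode, and its width $w$ (radians) fixes
the exponent through

$$k = 1 + \frac{1}{\tan^2(w/2)}, \qquad w = 2\pi N^{-1/3}.$$

The $N^{-1/3}$ shrinkage mirrors Scott-type reference rules for ordinary
histograms/KDEs: more models, narrower kernels. Each model contributes
with a Boltzmann-like weight derived from its total score $s_j$ (lower is
better),

$$c_j = e^{-s_j / s_\mathrm{ref}}, \qquad
P_i(\alpha) = \frac{1}{C} \sum_{j=1}^{N} c_j\, K(\alpha, \alpha_{ij}),
\qquad C = \sum_j c_j,$$

with $s_\mathrm{ref} = 10$ by default: weights change e-fold per 10 score
units, enough to damp the score differences among good models while
suppressing poor ones. The potential is the Boltzmann inversion

$$E_i(\alpha) = -f_i \ln P_i(\alpha),$$

with the scaling factor $f_i$ chosen per residue so that the standard
deviation of $E_i$ over the uniform angle grid is a fixed multiple of a
reference value: by default $14.77 \times \sigma_\mathrm{ref}$ for $\phi$
and $5.30 \times \sigma_\mathrm{ref}$ for $\psi$, where
$\sigma_\mathrm{ref}$ is the standard deviation of the corresponding
force-field proper-dihedral term (AMBER-style cosine series; see
`referenceTermStd()` for the closed form). That pins the restraint to
force-field magnitude. The force passed to the engine is the analytic
derivative $-dE/d\alpha = f_i\, P_i'/P_i$, evaluated in closed form from
the kernel sum and reported in kJ/mol/rad.

Omega angles can be extracted for diagnostics, but are never exported:
the planar peptide bond keeps them essentially constant, and the engine's
own terms should govern them.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `sRef` | 10 | score units | e-fold scale of the score weights |
| `w` | $2\pi N^{-1/3}$ | rad | kernel width; one global value per run |
| `gridStep` | 1 | degree | grid spacing of densities, energies, tables |
| `ratios` | 14.77 / 5.30 | – | target sd(E)/$\sigma_\mathrm{ref}$ for phi / psi |
| `stdRef` | user-supplied | kJ/mol | force-field reference sd; no guess is made |
| `floorEps` | 1e-8 | relative | density floor, as a fraction of the peak |
| `topFraction` | 1 | – | optional best-scoring subset before estimation |

Two of these deserve comment.

**`stdRef` is explicit.** Backbone phi and psi each map onto several
proper-dihedral types in AMBER-family force fields, and which one counts
as "corresponding" is a modelling decision. The package therefore takes
either a numeric `stdRef` or an explicit cosine-series term table and
never silently picks a force-field term itself.

**`floorEps` bounds the inversion.** Where the ensemble samples nothing,
$P \to 0$ and $-\ln P$ diverges. Densities are floored at
`floorEps * max(P)` before inversion, which caps the energy plateau and
zeroes the force there — unsampled regions become flat, not infinitely
repulsive. The floor, like every other knob, is recorded in the run
manifest.

**`topFraction`.** Whether all models or only a best-scoring subset
should feed the estimate is left to the user; the default uses every
provided model, on the grounds that the score weights already suppress
poor models smoothly and a hard cutoff would discard information the
weights can grade.

## Numerical choices

* **Angles** live in degrees in $[-180, 180)$ with $-180$ kept and $+180$
  wrapped — one canonical representative of the periodic boundary, so
  wrapping is idempotent. Inside the kernel the printed $\pi/360^\circ$
  conversion is applied literally; the $w \leftrightarrow k$ relation is
  evaluated in radians.
* **Torsion sign** follows IUPAC (cis = 0, trans = $\pm 180 \to -180$);
  the implementation agrees with `bio3d::torsion.xyz` to machine
  precision, and the signed torsion is invariant under chain reversal (a
  property the tests assert — the two half-planes are the same seen from
  either end).
* **Normalization** of $P_i$ is optional and recorded as a flag: it
  shifts $-\ln P$ by a constant, so forces — and, after the min-to-zero
  shift, energies — are unaffected. The tests assert exact force
  invariance.
* **Standard deviations** are population standard deviations over the
  uniform angle grid; the same uniform-angle measure underlies the
  closed-form reference-term standard deviation, so the two sides of the
  scaling ratio are measured identically.
* **Energy zero point**: each potential is shifted so its minimum is 0;
  additive constants are dynamically irrelevant.
* **Grids and tables**: densities are stored on $[-180, 180)$; exported
  tables append the $+180^\circ$ row (equal to $-180^\circ$) so the file
  covers the closed interval at 1° spacing. The third table column is
  the analytic force, not a finite difference of the second: a central
  difference at 1° spacing carries an $O(h^2)$ truncation error around
  $10^{-4}$ relative for these profiles, so derivative consistency is
  verified against small-step numerical differentiation of the energy
  function (step $10^{-3\circ}$, agreement $\le 10^{-6}$ relative), while
  the tables themselves stay exact.
* **Degenerate profiles** (flat density, e.g. an everything-floored
  residue) cannot be scaled and are skipped with a warning; the
  force-field term simply remains in place for them. Chain termini lack
  phi or psi and are likewise left untouched.

## The topology patch

`patchTopology()` removes every proper-dihedral line (function types 1
and 9, including all multiplicity lines, in either atom order) of the
targeted phi quadruplets $C_{i-1}\!-\!N_i\!-\!C\alpha_i\!-\!C_i$ and psi
quadruplets $N_i\!-\!C\alpha_i\!-\!C_i\!-\!N_{i+1}$, and adds one
tabulated-dihedral line (function type 8, scale 1.0 — the magnitude
already lives in the table) per quadruplet. Impropers,
Ryckaert–Bellemans terms, 1–4 pairs and omega are never touched. The
patch stores the removed lines with their original positions, so it is
reversible byte-for-byte and refuses to run twice (idempotent no-op with
a warning). Only pre-processed topologies are accepted; macros are an
error rather than a silent pass-through, because silently keeping a
force-field term next to a tabulated one would double-count the torsion.

## The synthetic-ensemble generator

The generator emulates the one thing downstream code consumes: a scored
multi-model PDB whose per-residue dihedral statistics are *known*. Angles
are drawn from per-residue von Mises mixtures (Best–Fisher sampling),
rebuilt into backbone coordinates by sequential internal-coordinate
construction with ideal bond lengths/angles and planar trans peptide
bonds, and paired with Gaussian scores, optionally coupled to the mixture
component so that one conformer family scores better. Everything runs
from a single mandatory seed; re-extraction reproduces the input angles
to well under 0.1°.

What it does **not** emulate: realistic sidechains (only N/CA/C/O are
built), correlated phi/psi (Ramachandran coupling), score physics, or
model-to-model atom heterogeneity. Passing tests on these fixtures
therefore demonstrate the estimator, the inversion, the scaling, the
export and the analytics — not that any particular experimental ensemble
is well described by independent per-residue mixtures.

Default study-scale conditions used across tests: mixtures with
concentration $\kappa \approx 8$ (a realistic backbone spread of roughly
20°), scores $\mathcal{N}(-100, 5^2)$ matching the scale on which an
$s_\mathrm{ref}$ of 10 acts, and ensembles of 1000 models for recovery
checks (kernel width $36^\circ$) — large enough for stable modes, small
enough that the whole suite runs in well under a minute per property.

## Analytics

* `circularSummary()`: weighted circular mean, resultant length,
  circular sd ($\sqrt{-2\ln\bar R}$), and KDE modes filtered by
  topographic prominence (default 5% of the peak, suppressing grid
  noise). With equal-mass antipodal clusters the mean is reported as
  undefined (`NA`) rather than an arbitrary direction.
* `subsetRmsd()`: superpose each model on one selection (least-squares
  rigid body, no reflection, via bio3d), then measure another — per-atom
  RMSD or centroid displacement, the convention used for ions and
  ligands. `krasRegions()` ships the KRAS preset (P-loop 10–17, Switch-I
  28–40, Switch-II 60–76, and their complement for fitting).
* `perResidueRmsf()`: fluctuation about the ensemble mean after fitting,
  averaged per residue.
* `combinedCsp()`: the conventional combined amide shift difference
  $\sqrt{\Delta\delta_H^2 + (0.2\,\Delta\delta_N)^2}$; the 0.2 nitrogen
  scale is a stated community convention, configurable and recorded by
  callers, not a value this package derives.

## Known limitations

* One global kernel width per run, even for residues sampled in fewer
  models — simpler provenance at the cost of per-residue adaptivity.
* No alternative kernels or cross-validated bandwidths; the estimator is
  deliberately fixed.
* No temperature appears in the inversion: $f_i$ absorbs all units, so
  the potentials are statistical restraints, not free energies.
* Topology support covers plain include-expanded files with one
  moleculetype of interest; preprocessing stays with the engine.
* Running the MD itself, solvation, clustering and validation of refined
  ensembles are out of scope: the package produces engine inputs and
  analyzes ensembles.

## A worked example

```{r example, eval = FALSE}
spec <- generatorSpec(
  nResidues = 6, nModels = 200,
  phi = data.frame(mode = -63, kappa = 8, mass = 1),
  psi = data.frame(mode = -43, kappa = 8, mass = 1),
  score = list(base = -100, sd = 5, coupling = 0), seed = 1)
files <- emitScoredEnsemble(spec, file.path(tempdir(), "demo"))

ens <- readScoredEnsemble(files$pdb, files$scores)
pefs <- buildTorsionPEFs(ens, stdRef = 1.86)   # e.g. from referenceTermStd()
tabs <- writeDihedralTables(pefs, file.path(tempdir(), "tables"))
# patchTopology(<preprocessed .top>, tabs) completes the MD input
```
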