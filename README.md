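# EnsemblePEF

Turn a scored protein structural ensemble — typically CS-Rosetta models
generated from NMR chemical shifts — into per-residue backbone torsion
potentials for molecular dynamics, and analyze ensembles before and after
refinement.

Generators like CS-Rosetta encode the experimentally grounded backbone
information in thousands of scored models, but cannot carry cofactors or
ligands. EnsemblePEF converts the ensemble's phi/psi statistics into
knowledge-based potentials that replace the force field's backbone proper
dihedrals, so an MD engine can complete and refine the model while staying
inside the conformational space the measurements support.

For each residue `i` and angle kind (phi or psi) with ensemble samples
`α_ij` and model scores `s_j`:

* score weights: `c_j = exp(−s_j / s_ref)`, `s_ref = 10` by default;
* circular KDE with a power-raised cosine kernel:
  `P_i(α) = (1/C) Σ_j c_j · cos^k(Δ(α, α_ij) · π/360°)`, where `Δ` is the
  circular distance in `[0°, 180°]`, `k = 1 + 1/tan²(w/2)`, and the width
  follows a Scott-like rule `w = 2π·N^(−1/3)`;
* Boltzmann inversion: `E_i(α) = −f_i · ln P_i(α)`, with `f_i` set per
  residue so that sd(E) equals 14.77 (phi) or 5.30 (psi) times the standard
  deviation of a reference force-field dihedral term;
* analytic forces `−dE/dα = f_i · P_i′/P_i` in kJ/mol/rad, exported as
  three-column tabulated dihedral files plus a reversible topology patch
  that swaps the targeted propers for tabulated terms (omega untouched).

A seeded synthetic-ensemble generator (von Mises mixtures, ideal-geometry
backbone reconstruction, controllable score–conformer coupling) makes every
stage testable with known ground truth. Analysis helpers cover circular
summaries and mode counts, subset RMSD after fitting a different subset
(e.g. an ion against the non-Switch backbone of KRAS; presets included),
per-residue RMSF and combined chemical-shift perturbations.

## Worked example

```r
library(EnsemblePEF)

spec <- generatorSpec(
  nResidues = 6, nModels = 200,
  phi = data.frame(mode = -63, kappa = 8, mass = 1),
  psi = data.frame(mode = -43, kappa = 8, mass = 1),
  score = list(base = -100, sd = 5, coupling = 0), seed = 1)
files <- emitScoredEnsemble(spec, file.path(tempdir(), "demo"))

ens <- readScoredEnsemble(files$pdb, files$scores)
ens
#> ScoredEnsemble: 200 models, kinds {phi, psi}, 2000 dihedral samples
#>   scores: min -113.32, median -100.52, max -86.04
kernelConfig(N = nModels(ens))
#> CircularKernelConfig: w = 1.07441 rad (61.56 deg), k = 3.8186, N = 200

pefs <- buildTorsionPEFs(ens, stdRef = 1.86)
pefs[["3:phi"]]
#> TorsionPEF: residue 3 phi, f = 15.1521, sd(E) = 27.472 kJ/mol, 0 floored points
```

The scaling contract is visible directly: 27.472 = 14.77 × 1.86, i.e. the
potential's standard deviation is exactly 14.77 reference units. The
minimum sits at the density mode:

```r
p <- pefs[["3:phi"]]
angleGrid(p)[which.min(energyValues(p))]
#> [1] -64          # generating mode was -63 deg
circularSummary(dihedralSamples(ens, residue = 3, kind = "phi")$angle)[c("mean", "sd", "nModes")]
#> $mean -63.2   $sd 19.6   $nModes 1
```

Export for the MD engine:

```r
tabs <- writeDihedralTables(pefs, "tables")      # table_d0.xvg, ...
res  <- patchTopology("protein_pp.top", tabs)    # preprocessed topology
writeLines(res$lines, "patched.top")
```

A command-line front end with `synth`, `extract`, `pef`, `export-gromacs`
and `analyze` subcommands lives in `inst/scripts/ensemblepef.R`.

## Scope

The package produces MD inputs and analyzes ensembles; running simulations,
solvation, trajectory clustering and structure validation belong to the MD
suite and are out of scope, as are NMR acquisition and running CS-Rosetta
itself.
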