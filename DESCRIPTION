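Package: EnsemblePEF
Title: Ensemble-Derived Circular Torsion Potentials for Molecular Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts scored protein structural ensembles (for example
    CS-Rosetta models generated from NMR chemical shifts) into per-residue
    backbone phi/psi torsion potentials. Dihedral angles are pooled across
    models, turned into score-weighted circular kernel density estimates
    with a power-raised cosine kernel, Boltzmann-inverted into potential
    energy functions with analytic forces, scaled to force-field magnitude,
    and exported as MD-engine tabulated dihedral potentials together with a
    topology patch that swaps the force field's backbone proper dihedrals
    for the new tabulated terms. Also provides ensemble-comparison
    analytics (circular summaries, subset RMSD after fitting a different
    subset, per-residue RMSF) and a seeded synthetic-ensemble generator
    with known dihedral statistics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
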