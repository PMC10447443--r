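Package: ShiftEnsemble
Title: Chemical-Shift-Driven Ensemble Selection for Amorphous Molecular Solids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Determines ensemble atomic-level structures of amorphous molecular
    solids by scoring local molecular environments from molecular-dynamics
    snapshots against experimentally measured NMR chemical-shift distributions.
    Each environment is assigned the probability that its predicted 1H/13C
    shifts are drawn from the experimental distributions (Z-score two-tailed
    p-values, penalized by prediction uncertainty relative to the per-site
    first-quartile uncertainty, combined as a geometric mean), and the
    best-matching "NMR ensemble" is selected by probability threshold or top
    fraction. The selected ensemble is characterized structurally: hydrogen
    bonds, dihedral conformer populations, least-RMSD-aligned 3D atomic density
    maps, radial distribution functions, and formation energies through a
    pluggable single-point energy backend. A self-contained synthetic-data
    generator produces periodic amorphous packings of a toy flexible molecule
    with planted conformer and hydrogen-bond subpopulations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, graphics, bio3d
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
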