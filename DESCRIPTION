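Package: octaggr
Title: Aggregation of Aromatic Pollutants in n-Octanol and Apparent K_OA Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for studying pi-stacking aggregation of
    aromatic pollutants (PCBs, PAHs, PBDEs, PCNs, PCDDs) dissolved in the
    n-octanol phase, and the effect of aggregation on the apparent
    n-octanol-air partition coefficient (K_OA). Provides saturated-solubility
    and box-composition arithmetic from water solubility and K_OW, readers and
    writers for periodic-box molecular trajectories (GRO, multi-frame XYZ,
    PDB) with explicit molecule grouping, detection and census of face-to-face,
    offset face-to-face and edge-to-face stacked aggregates under periodic
    boundary conditions, an aggregation-corrected apparent log K_OA estimator
    from solvation free energies, generators for planted-cluster conformations
    and dynamic-equilibrium trajectories, and a square-well Metropolis Monte
    Carlo toy model of reversible solute association.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
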