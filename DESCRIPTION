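Package: samscan
Title: Rigid-Body Orientation Screening of Proteins on SAM-Coated Gold Electrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale modelling of how a charged protein adsorbs on an
    amino-alkanethiol self-assembled monolayer (SAM) covering a gold
    electrode. Builds a SAM-on-Au(111) slab with a configurable protonated
    headgroup fraction, samples rigid-body protein orientations on a
    (theta, psi) grid, evaluates in vacuo Coulomb plus Lennard-Jones
    interaction energies, constructs the orientation energy landscape and
    selects the energetically favourable adsorption poses. Per-orientation
    observables include the protein macrodipole (Debye), its angle to the
    surface normal, cofactor-to-surface distances, optimal-superposition
    RMSD, dipole-field re-ranking around the potential of zero charge,
    directional statistics of dipole pseudo-trajectories, and monolayer
    surface-coverage estimates (hexagonal packing and de Feijter).
    Includes deterministic synthetic generators (dumbbells, patchy spheres,
    planted two-basin landscapes, von Mises-Fisher dipole trajectories)
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
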