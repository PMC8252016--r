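Package: rxesim
Title: Ligand-Field Multiplet Simulation of Kbeta X-Ray Emission and 1s3p
    Resonant X-Ray Emission Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Atomic and ligand-field multiplet machinery for non-resonant
    Kbeta X-ray emission (XES) and resonant 1s3p X-ray emission (RXES/RIXS)
    of high-spin 3d^n transition-metal ions, aimed at iron model complexes
    and iron-sulfur clusters. Enumerates Russell-Saunders terms and their
    core-hole couplings, builds and diagonalizes determinant-basis
    Hamiltonians (Slater-Condon Coulomb, spin-orbit, cubic ligand field),
    evaluates spin-conserving one-electron transition amplitudes, computes
    Kramers-Heisenberg RXES planes with constant-incident-energy and HERFD
    cuts, and provides the spectral post-processing used to assign physical
    oxidation states: normalization, ferric-reference difference spectra,
    peak/shoulder detection, exchange-splitting metrics, and Slater-Condon
    covalency scans. Includes ferrous/ferric site presets, weighted
    multi-site mixtures emulating mixed-valent dimers and cubanes, and
    seeded pseudo-measurement generation.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'rxesim-package.R'
    'wigner.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'terms.R'
    'basis.R'
    'hamiltonian.R'
    'amplitudes.R'
    'spectra.R'
    'analysis.R'
    'presets.R'
    'io.R'
    'cli.R'
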