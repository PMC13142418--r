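Package: rthf
Title: Real-Time Hartree-Fock Absorption Spectra for Protein-Embedded
    Chromophores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes electronic absorption spectra of chromophores embedded
    in proteins with a fully quantum-mechanical treatment of the surrounding
    residues.  A quantum region is carved from a protonated PDB structure
    (ligand plus all atoms within a distance cutoff, cutting only
    carbon-carbon single bonds and capping them with hydrogens), the total
    charge is selected by a Mulliken-population scan with a stability test,
    and the restricted Hartree-Fock ground state in the minimal STO-3G basis
    is perturbed by an instantaneous dipole kick and propagated in real time
    with a predictor-corrector exponential-midpoint integrator.  Damped
    Fourier transforms of the induced dipole give per-direction and isotropic
    absorption spectra, peak tables, constant-shift calibration against
    experiment, and per-atom absorption maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
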