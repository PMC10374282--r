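Package: fusedyn
Title: Multi-Modal Analysis of Protein Conformational Heterogeneity and Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to resolve conformational heterogeneity and exchange
    dynamics of multi-domain proteins by fusing complementary solution
    measurements. Implements accessible-volume and accessible-contact-volume
    simulation of dye and spin labels on coarse structures; forward models
    and global fitting of ensemble TCSPC fluorescence decays via the
    FRET-induced donor decay, with maximum-entropy distance reconstruction
    and FRET-lines; DEER dipolar-kernel simulation and Tikhonov inversion
    with L-curve selection; filtered-FCS species correlation functions and
    global kinetic fitting with shared relaxation times; rigid-body
    neutron spin-echo models (6x6 diffusion tensor, spherical-harmonic
    expansion, cumulant analysis, hydrodynamic corrections); SAXS forward
    scattering, concentration-series reduction, Percus-Yevick structure
    factors and two-state ensemble fits; and discrimination of candidate
    conformer pairs by chi-square scoring of distance restraints combined
    with SAXS evidence through Fisher's method. A synthetic-data module
    generates toy two-conformer systems and statistically faithful data for
    every modality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
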