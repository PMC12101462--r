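Package: xtaltherm
Title: Finite-Temperature Thermodynamics of Molecular Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sublimation enthalpies of molecular crystals at three levels of
    theory over a pluggable interatomic-potential interface: quasi-harmonic
    phonon thermodynamics with small-displacement force constants, classical
    Langevin molecular dynamics in the NVT and NPT ensembles, and path-integral
    molecular dynamics with normal-mode integration, PILE thermostatting and
    the centroid-virial kinetic-energy estimator.  Includes Birch-Murnaghan
    equation-of-state scans, reblocking error analysis for correlated time
    series, a data-efficient training-set sampling loop for fitting surrogate
    potentials, hydrogen-bond isotope (Ubbelohde) analysis, and packaged
    analytic toy potentials so that every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
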