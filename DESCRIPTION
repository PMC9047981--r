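Package: smdcycle
Title: Absolute Binding Free Energies from Steered Simulations over
    Restrained Thermodynamic Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating absolute protein-protein binding free
    energies with the steered-molecular-dynamics (SMD) confinement
    strategy: a Langevin engine for restrained toy dimer systems, the
    Jarzynski nonequilibrium work estimator with bootstrap errors,
    assembly of a fictitious thermodynamic cycle (two restraint-release
    processes plus one restrained pulling process) with standard-state
    and rotational-restriction corrections, and structural interface
    analysis (solvent-accessible surface area, pi-pi stacking and
    hydrogen-bond detection with per-frame occupancy, and alanine
    truncation mutant construction). Exact one-dimensional quadrature
    oracles and synthetic structure fixtures support validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
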