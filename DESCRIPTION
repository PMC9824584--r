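Package: chainexpand
Title: Langevin Dynamics and Two-Stage Kinetics of Polymer Chains Released
    from Spherical Confinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained bead-spring Langevin dynamics of a single polymer
    chain confined in, and then released from, a reflecting spherical cavity,
    as a minimal model of viral genome release. Provides the WCA plus
    harmonic-bond force field, a BAOAB Langevin integrator with cell-list
    neighbour search, reproducible replica-ensemble management, ensemble
    observables (radius of gyration, gyration-tensor eigenvalues, asphericity
    and prolateness, expansion velocity), the closed-form two-stage expansion
    laws (spherical swelling followed by coil expansion), diagnostic
    statistics and iterative Levenberg-Marquardt fits for the characteristic
    times, power-law exponent estimation, master-curve scaling collapse, a
    synthetic-ensemble generator for fit validation, and XYZ/delimited-text
    input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
SystemRequirements: C++17
RoxygenNote: 7.3.3
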