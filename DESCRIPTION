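Package: remdkin
Title: Kinetic Analysis of Replica Exchange Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting Markov-state kinetics from temperature
    replica exchange molecular dynamics (REMD) data. Provides a synthetic
    REMD generator (Metropolis neighbour swaps over a temperature ladder
    driving a continuous-time Markov jump process with Arrhenius rates and
    Gaussian observable emissions), demultiplexing between per-replica and
    per-temperature trajectories, convergence diagnostics (exchange
    acceptance, the equal-occupancy rule, and detection of non-Gaussian
    potential-energy distributions induced by external electric fields),
    transition-based state assignment on a one-dimensional reaction
    coordinate, and master-equation rate estimation by direct transition
    counting with block-averaged errors, stationary populations from the
    zero-eigenvalue eigenvector, and propagator consistency checks between
    replica and temperature trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    mclust,
    yaml,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
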