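Package: branchtax
Title: Stochastic Simulation of Branched Cell Migration and Chemotaxis on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Coarse-grained stochastic model of amoeboid cells migrating as
    branched shapes on edge networks (single junctions and hexagonal
    lattices). Each cellular arm carries slip-bond adhesion, actin
    treadmilling flow with Ornstein-Uhlenbeck noise, and a conserved
    inhibitory polarity cue advected by the net flows along the
    one-dimensional branched cell body. The package provides the
    Euler-Maruyama simulator (compiled core), analytic criticality results
    (spreading and polarization lengths, critical actin activities),
    chemokine field models with saturating response, trajectory metrics for
    decision-making and chemotaxis statistics (escape and arrival times,
    error rates, forward migration index, stick-slip and slow-mode event
    detection), and reproducible protocol runners for junction sweeps,
    network sweeps, gradient-onset reorientation, and cytoskeletal drug
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
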