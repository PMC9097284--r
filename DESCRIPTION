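Package: hydrokin
Title: Stochastic Kinetics of Solvent Exchange in Ion Hydration Shells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model water-exchange kinetics in the first coordination
    shell of aqua ions along the continuous coordination-number coordinate.
    Estimates free-energy profiles F(s) from sampled trajectories, partitions
    the coordinate into coordination states, assigns frames to states with a
    history-based rule, and estimates the position-dependent diffusion
    coefficient D(s) from short-trajectory transition statistics via a
    propagator / rate-matrix construction with a detailed-balance error
    estimate. Mean first-passage times between coordination states are
    computed by four mutually validating routes: Crank-Nicolson integration
    of the 1D Smoluchowski (Fokker-Planck) equation, the backward-Kolmogorov
    double integral, the Kramers high-barrier approximation, and replica
    overdamped Langevin simulation (Euler-Maruyama, compiled). Committor
    (splitting-probability) analysis validates the coordination number as a
    reaction coordinate. Includes a synthetic-landscape generator with
    ion-like presets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
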