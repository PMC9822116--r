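Package: mesoreplay
Title: Mesoscopic Stochastic Neural Mass Models with Short-Term Plasticity
    and Ring-Attractor Replay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded simulators for a bottom-up hierarchy of neural population
    models with Tsodyks-Markram short-term synaptic plasticity: microscopic
    networks of linear-nonlinear-Poisson (LNP) spiking neurons, the derived
    mesoscopic diffusion and jump-diffusion (hybrid Poisson-Gaussian noise)
    Langevin models, and the deterministic macroscopic limit. Includes
    ring-attractor connectivity for single and multiple circular environments,
    phase-plane analysis of the macroscopic system (fixed points, linear
    stability, invariant manifolds), and a statistics battery for metastable
    population dynamics: population-spike and burst detection, interburst
    interval cumulants, nonlocal replay event kinematics with population
    vector average decoding, Up/Down state segmentation, serial correlations,
    and multi-environment replay sequence statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
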