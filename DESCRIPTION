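Package: doponet
Title: Spiking Neural Networks of Paired Degenerate Optical Parametric Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of artificial spiking neurons built from
    antisymmetrically coupled pairs of degenerate optical parametric
    oscillators (DOPOs). Provides fixed-step integrators for the full
    two-variable (v, w) amplitude dynamics and for the reduced
    phase-amplitude and Kuramoto forms, closed-form spiking-frequency and
    steady-amplitude laws, linear-stability and bifurcation classification
    (Andronov-Hopf versus saddle-node-on-limit-cycle), builders for
    clustered Kuramoto-style ensembles and Ising-encoded networks,
    observables (spike trains, order parameter, Ising and local energies,
    renormalized pump diagnostics), and a pump-ramp annealing heuristic for
    Ising-model combinatorial optimization with an exact brute-force oracle
    for small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
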