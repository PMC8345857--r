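Package: tauspread
Title: Directional Bias in Tau Deposition from Axonal Transport Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the spatiotemporal dynamics of soluble and insoluble
    pathological tau in a one-dimensional, five-compartment two-neuron system
    (presynaptic somatodendritic compartment, axon initial segment, axon,
    synaptic cleft, postsynaptic somatodendritic compartment). Soluble tau
    diffuses and undergoes kinesin-driven active transport whose effective
    velocity is modulated by local tau concentrations; the two species
    interconvert through aggregation and fragmentation. The package provides
    a conservative finite-volume discretization integrated with stiff
    method-of-lines solvers, steady-state diagnostics, somatodendritic bias
    statistics, zero-bias manifold analysis over the transport feedback
    parameters, interconversion-rate calibration, and a generic harness for
    fitting model parameters to observed bias time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
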