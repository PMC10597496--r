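Package: onevent
Title: Event-Based Simulation of Conductance-Based Point Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete, on-event simulation of conductance-based point
    neurons. Hodgkin-Huxley and Wang-Buzsaki single-compartment models
    with single-exponential synapses serve both as ground truth and as
    the core of "on-event" oracle functions that map a limited window of
    recent synaptic events to a next-spike-time. The package provides
    Poisson stimulus generation, state-variable frame libraries, the
    on-event scheduler, spike-train and response-distribution metrics
    (spike prediction coherence, next-spike-time dispersion, determinism
    categories, van Rossum distance, spike-triggered variance), and
    seeded experiment drivers quantifying how response determinism,
    spike-train fidelity and state reconstructability grow with the
    number of known recent events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
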