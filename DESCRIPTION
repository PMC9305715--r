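Package: ddmfruit
Title: Density-Dependent Fruit Growth from Source-Sink Sugar Sharing
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Kinetic source-sink model of fruit growth in which a population
    of n sink individuals (cells, seeds, fruits, or plants) shares sugar
    delivered by Muench-style phloem mass flow. Sugar flow is driven by the
    source-sink concentration gradient through a conductance that scales with
    population size as kappa*n^alpha; unloading at the sink follows
    Michaelis-Menten kinetics (Vm, Km); individual dry mass grows by hourly
    forward-Euler integration of the unloaded carbon net of respiration.
    Provides density-response analysis (a density-dependence index and
    under/exact/over-compensation classification), parameter estimation by a
    real-coded genetic algorithm minimizing the sum of squared errors with
    multi-restart and RRMSE reporting, a synthetic-data generator emulating
    observation sets at five levels of organisation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
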