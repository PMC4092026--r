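Package: liquidmetrics
Title: Reservoir Metrics and Synaptic Plasticity in Spiking Liquid State Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates spiking Izhikevich-neuron reservoirs (liquid state
    machines) under three connectivity models (uniform random, scale-free,
    distance-based 3D lattice) and three unsupervised synaptic plasticity rules
    (BCM, bi-phasic STDP, tri-phasic STDP), trains a least-mean-squares linear
    readout for time-series classification, and computes four reservoir quality
    metrics: class separation, kernel quality (state-matrix rank), a Lyapunov
    exponent estimate, and spectral radius. Provides synthetic benchmark
    generators (a tri-function switching signal and a surrogate nine-speaker
    vowel dataset), a full experiment grid runner, and tidy summaries of how
    each metric correlates with classification accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    readr,
    ggplot2,
    generics,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
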