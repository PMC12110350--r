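Package: epiastro
Title: Astrocyte-Neuron Coupled Epileptic Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates seizure dynamics on Watts-Strogatz small-world networks of
    excitatory/inhibitory neural populations coupled to astrocytes through
    calcium-gated glutamate feedback. Provides four single-parameter discharge
    modes (quiescent, high-frequency oscillatory, intermittent, saturated),
    two in-silico treatment strategies (waveform stimulation of high-degree
    nodes and surgical resection of discharge-mode node groups), and
    synchronization metrics (Hilbert-phase phase-locking value, Kuramoto order
    parameter, coefficient of variation) together with glutamate load summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    patchwork,
    zoo
Config/testthat/edition: 3
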