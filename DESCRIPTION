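Package: synadapt
Title: Dynamic Information Encoding with Dynamic Synapses in Adapting
    Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a recurrent network of leaky integrate-and-fire
    neurons with spike-frequency adaptation and Tsodyks-Markram short-term
    plasticity at excitatory synapses, together with a balanced downstream
    read-out neuron. Provides the experiment protocol for studying how
    stimulus information migrates from firing rates to weak synchronized
    correlations during adaptation: trial batches under default, transient,
    static-synapse and plasticity-variant conditions, a bin-shuffling
    control for input currents, and a dichotomized Gaussian population
    model (with a Monte Carlo sampling oracle) that quantifies pairwise
    input correlations and the population synchrony distribution. Includes
    period-wise statistics, paired significance tests, PSTHs and read-out
    spike-count summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
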