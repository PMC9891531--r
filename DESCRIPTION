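Package: decouplr
Title: Decoupling Interacting Neuronal Populations by Time-Shifted Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating time-shifted two-site
    stimulation protocols that decouple reciprocally connected neuronal
    populations through spike-timing-dependent plasticity (STDP). Provides a
    closed-form theory of the per-period net synaptic change for a pair of
    periodically firing neurons with dendritic and axonal transmission delays,
    a clock-driven leaky integrate-and-fire (LIF) simulator for two sparsely
    connected excitatory-inhibitory modules coupled by plastic delayed
    excitatory synapses, generators for burst and continuous time-shifted
    pulse-train protocols, and a suite of synchrony and coupling metrics
    (population Fano factor, spike-count correlations, inter-spike-interval
    irregularity, spectral peaks, phase lags). Figure-level experiment presets
    and parameter sweeps reproduce the decoupling and desynchronization
    regimes of the underlying model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
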