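Package: stdpnet
Title: Integrate-and-Fire Network Simulation of Stimulation-Induced Cortical Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a three-column cortical network of integrate-and-fire units
    with spike-timing-dependent plasticity (STDP) and motoneuron pools, and the
    closed- and open-loop conditioning protocols used in bidirectional
    brain-computer-interface experiments: spike-triggered, EMG-triggered,
    cycle-triggered (beta-phase), gamma-triggered, paired-pulse, tetanic, and
    spike-triggered inhibition. Provides evoked-potential measurement on simulated
    local field potentials, EMG synthesis with a motor-unit size principle,
    trigger-aligned histograms, and connection-weight tracking. The stepping core
    is written in C++ for speed; all randomness flows through R's RNG so runs are
    reproducible from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
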