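Package: pcmnet
Title: Phase-Change-Memory Synapses, STDP, and Spiking-Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compact-model simulation of one-transistor/one-resistor (1T1R)
    phase-change-memory (PCM) synapses with spike-timing dependent plasticity
    (STDP), and of fully connected leaky-integrate-and-fire (LIF) networks
    that learn, forget and update 28x28 visual patterns without supervision.
    Includes the overlap-based STDP protocol with rectangular PRE/POST
    waveforms, an epoch-driven engine for 2- and 3-layer networks with
    noise-driven background depression and lateral inhibition, digit-like
    stimulus fixtures plus PGM/CSV/IDX bitmap readers, recognition statistics
    (recognition and error probabilities), and synaptic energy and power
    accounting including the pulsed-read duty-cycle scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
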