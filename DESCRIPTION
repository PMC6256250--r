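Package: enstdp
Title: Energy-Constrained Spiking Networks with Metabolically Gated STDP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of leaky integrate-and-fire neurons
    whose excitatory synapses evolve under a three-factor spike-timing-dependent
    plasticity rule gated by each neuron's metabolic energy budget. Every neuron
    tracks the ATP cost of synaptic transmission and of action-potential
    generation through alpha-function energy kernels; the ratio of transmission
    energy to total signaling energy over a sliding window multiplicatively
    modulates STDP so that neurons are driven toward a fixed energy set point.
    Provides Dale-constrained random network construction, Poisson and periodic
    stimulus generation, a fast clock-driven simulation engine, and scripted
    experiments relating synapse counts, network size, and steady-state synaptic
    weights under the energy constraint.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
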