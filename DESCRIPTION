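Package: hrmas
Title: Architecture Search for Recurrent Spiking Neural Networks with
    Locally Recurrent Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates discrete-time leaky integrate-and-fire (LIF) recurrent
    spiking neural networks whose hidden layer is tiled by small recurrent
    motifs with sparse corresponding-neuron links between neighbours
    (a sparsely-connected recurrent motif layer, SC-ML), and optimizes the
    layer topology with a hybrid risk-mitigating architecture search (HRMAS):
    softmax-relaxed motif-size and connection-type choices trained by
    surrogate-gradient backpropagation through time, a second-order bi-level
    (one-step look-ahead) architecture update computed with finite
    differences, and an intrinsic-plasticity rule (SpiKL-IP style) that
    adapts each neuron's leak resistance and membrane time constant toward a
    target firing rate between architecture updates. Includes synthetic
    spike-train task generators (jittered spatiotemporal patterns and a
    teacher network with a planted motif size), ablation modes, a random
    search baseline, plain-text dataset and architecture file formats, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
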