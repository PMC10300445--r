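Package: snnwm
Title: Spiking Neural Networks with Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time leaky integrate-and-fire (LIF) spiking neural
    networks extended with multi-delay dendrites, factorized temporal
    kernels, windowed working-memory rectification and a temporal fusion
    readout, trained by surrogate-gradient backpropagation through time.
    Includes rate/latency/direct spike encoders, synthetic temporal-order
    and spike-density classification tasks, closed-form parameter and
    state-memory access cost models, and an experiment harness for
    memory-length sweeps.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
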