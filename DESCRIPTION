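Package: sinres
Title: Computation in Sine-Activation Random Recurrent Networks Beyond the Fixed Point
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates random recurrent neural networks (reservoirs) with a
    sinusoidal activation function driven by, and trained to predict, the
    chaotic Mackey-Glass time series. Provides the Mackey-Glass discrete-map
    generator, pseudoinverse readout training with closed-loop free-running
    prediction, and a set of complexity indices resolved along the feedback
    gain mu: normalized mean squared prediction error, autonomous-output
    suppression, spatial synchronization error, histogram mutual-information
    memory capacity, and maximal Lyapunov exponents estimated by the
    Rosenstein nearest-neighbour method. Includes Takens delay-embedding
    utilities (auto-mutual-information delay selection, false-nearest-neighbour
    dimension selection), bifurcation scans with regime classification, and
    tidy scan orchestration with realization averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
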