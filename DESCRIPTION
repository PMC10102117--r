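Package: mixedsel
Title: Nonlinear Mixed Selectivity Analysis of Neural Populations in a
    Delayed Match-to-Sample Navigation Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how single neurons and neural populations
    encode task variables in a virtual-navigation delayed match-to-sample
    task. Provides a synthetic-session generator (trials, maze trajectories,
    ground-truth binarized event trains), Poisson encoding models with
    raised-cosine position and velocity bases fitted by elastic-net
    regularization, single-trial log-likelihood-ratio information for the
    sample cue, test cue, and their XOR (the reward direction), selectivity
    classification in information polar coordinates, a nonlinearity index of
    trial-type tuning, likelihood-based population decoding with
    confusion-matrix mutual information, signal/noise correlation tools with
    within-condition shuffling, a Gaussian-copula correlated-Poisson
    simulation comparing mixed- versus pure-selectivity population codes,
    behavioral bias indices, and bootstrap inference utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
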