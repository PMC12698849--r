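Package: splitfedlab
Title: Split Federated Learning, Label Inference Attacks, and
    Differential-Privacy Noise Defenses for Medical Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An in-process simulator of split federated learning (SplitFed)
    for multi-class medical-image classification, built around a small
    convolutional network with exact parameter-gradient access. Implements
    the gradient-matching label inference attack, in which an adversary
    holding a clone of one model part enumerates candidate labels and selects
    the one whose clone gradients best match observed per-sample parameter
    gradients, and an additive-noise defense that injects Gaussian, Laplace,
    Cauchy, or exponential noise into model parameters, transmitted
    activations and gradients, or the update rule. Includes a synthetic
    brain-MRI-like image generator so the full pipeline (training, attack,
    privacy/utility sweeps) runs without external data, plus classification
    and attack metrics, noise-type sweep experiments, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
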