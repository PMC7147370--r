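Package: stochact
Title: Stochastic Activation-Layer Replacement and Sum-Rule Ensembles for
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A catalogue of ten static and learnable activation functions
    (ReLU, Leaky ReLU, ELU, PReLU, SReLU, APLU, and the Mexican-hat and
    Gaussian piecewise-linear families MeLU, wMeLU, GaLU, sGaLU) with exact
    forward values, analytic gradients with respect to inputs and learnable
    parameters, and the published initializations; a model-surgery layer
    that replaces the activation layers of a convolutional network either
    uniformly or by independent stochastic draws from a pool; sum-rule
    ensemble fusion for classification and pixel-level vote fusion for
    segmentation masks; a training and evaluation harness (accuracy,
    pixel-level F1, exact Wilcoxon signed-rank comparison); and a synthetic
    image generator plus a tiny CNN so the whole pipeline is testable on one
    CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
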