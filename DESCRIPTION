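Package: enosebox
Title: Open-Set Odor Classification for Gas-Sensor Electronic Noses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for open-set classification of electronic-nose (gas-sensor
    array) measurements, where odors from classes never seen in training must
    be rejected rather than forced into a trained class. Implements a
    minimum-maximum-mean (MMM) hyperbox classifier with a reject option and
    validation-driven boundary expansion, together with from-equation
    reference implementations of five comparator classifiers (k-nearest
    neighbor, pairwise linear support vector machine, multilayer perceptron,
    generalized regression neural network, and radial basis function network),
    principal component analysis for score plots, an open-set evaluation
    protocol (misclassification, false classification, and correct-rejection
    rates), and a synthetic data generator emulating an 8-sensor, 12-class
    fruit-odor experiment with controllable separation between trained and
    irrelevant odor classes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    kernlab,
    MASS,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
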