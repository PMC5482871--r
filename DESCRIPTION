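Package: hiercls
Title: Hierarchy-Constrained Deep Metric Classification for Histopathology Images
Version: 0.1.0
Authors@R:
    person("hiercls", "developers", email = "hiercls@example.org", role = c("aut", "cre"))
Description: Multi-class classification of histopathology images under a
    two-level benign/malignant tumour-type label hierarchy. Implements a
    combined objective of softmax cross-entropy and a hierarchical quadruplet
    distance-constraint hinge loss on l2-normalised embeddings, taxonomy-aware
    quadruplet mining, patient-level and image-level recognition rates,
    patient-wise stratified splitting and cross-validation, class-balancing
    oversampling with intensity/rotation/flip/translation augmentation, a
    small convolutional backbone trained by stochastic gradient descent with
    momentum, and a synthetic hierarchical image generator so the full
    pipeline is testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
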