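Package: decodyn
Title: Temporal-Generalization Decoding of Deep, Distributed, Dynamic Neural Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a recurrent hub-and-spokes semantic network settling on
    visual and verbal patterns, generates a synthetic electrocorticography
    (ECoG) cohort with a category code that is spatially stable at posterior
    electrodes and rotates nonlinearly at anterior ones, and provides a
    sliding-window temporal-generalization decoding engine (plain and
    L1-regularized logistic classifiers with nested cross-validation) together
    with the statistics that characterise a dynamic neural code: constant
    decodability, local temporal generalization with overlapping waves of
    classifier clusters, a widening generalization window assessed by
    piecewise-linear regression with BIC model selection, and an
    anterior-posterior gradient in the variability of change (VoC) of decoder
    coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
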