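Package: ovotherm
Title: Egg Freshness Detection from Infrared Thermal Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for non-destructive egg freshness grading from active
    infrared thermography of the egg blunt end. Implements the spherical-crown
    projection geometry that links the air-cell height to the elliptical hot
    region seen in thermal images, an axisymmetric transient heat-conduction
    simulator of the blunt end under hot-air excitation, a synthetic
    pseudo-colored thermal video generator with ground truth, two
    feature-extraction routes (edge/ellipse parameters and connected-domain
    plus gray-level co-occurrence texture statistics), and multi-class
    freshness classifiers (naive Bayes, k-nearest neighbours, decision tree,
    random forest, support vector machine) with confusion-table evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    png,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
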