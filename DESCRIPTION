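Package: ppgexplain
Title: Explainability Metrics for Convolutional PPG Quality Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global, quantitative explainability metrics for convolutional
    classifiers of photoplethysmography (PPG) signal quality. Saliency-derived
    attention maps are compared against expert artifact annotations via two
    metrics: Congruence, the proportion of attention mass falling inside
    annotated regions, and Annotation Classification, the AUROC obtained when
    attention scores are thresholded to predict whether a pixel, an
    annotation-delimited section, or a fixed-length interval is annotated.
    Includes gradient-based attribution methods (integrated gradients, guided
    backpropagation, and an expected-gradients difference-from-reference
    attribution), a compact trainable 1D residual convolutional network,
    synthetic PPG/annotation/attention generators with known ground truth, and
    study drivers for model comparison and explainability-versus-performance
    correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
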