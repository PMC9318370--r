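Package: hrvaf
Title: Minimal Heart-Rate-Variability Feature Sets for Atrial Fibrillation
    Detection in 60-Second RR-Interval Segments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how few time-domain heart-rate-variability (HRV)
    descriptors are needed to separate atrial fibrillation (AF) from sinus
    rhythm (SR) in short RR-interval segments.  Provides a seeded generator of
    annotated two-rhythm RR cohorts, segmentation of recordings into pure
    60-second windows with artifact filtering, thirteen gap-aware HRV
    descriptors (pRR50, Poincare SD1/SD2 and their ratio, SDRR, CV, RRdif,
    relRRdif, successive-ratio statistics, mean RR, RRrange, relRRrange),
    per-feature ROC-AUC ranking and a from-scratch minimum-redundancy
    maximum-relevance (MRMR) selector based on binned mutual information, and
    a patient-disjoint classifier-evaluation harness (decision tree, K nearest
    neighbours, linear and RBF support vector machines, AdaBoost, random
    forest, single-hidden-layer neural network) with 5-fold cross-validated
    metaparameter tuning, blindfold validation on held-out patients, and
    diagnostic metrics including the diagnostic odds ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    nnet,
    ranger,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
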