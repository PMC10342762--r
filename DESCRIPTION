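Package: fuzzybiopsy
Title: Fuzzy-Rule Cascade Prediction of Targeted Prostate Biopsy Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Personalized prediction of MRI-targeted (fusion) prostate biopsy
    outcomes from prebiopsy variables. A fuzzy inference system is induced
    automatically from training data by per-class self-organizing-map
    clustering, FP-growth frequent-itemset mining on interval-binarized
    variables, and class-predominance filtering of the mined rules; patients
    matched by no fuzzy rule are classified by a linear-kernel support vector
    machine in cascade, so every patient receives a label together with the
    IF-THEN rules that explain it. Includes Gower-distance KNN exhaustive
    feature-subset selection, a synthetic-cohort generator emulating the
    development population, and an evaluation battery (confusion metrics,
    ROC with optimal thresholds, decision-curve analysis, logistic-regression
    and univariate PSA/PSA-density/PI-RADS baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
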