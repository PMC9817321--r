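Package: lungflv
Title: Functional Lung Volume CT Analysis and Predicted Postoperative
    Spirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative computed-tomography lung volumetry by
    Hounsfield-unit thresholding: total lung volume (TLV, -1024..-500 HU
    with tracheal air removed) and functional lung volume (FLV,
    -910..-600 HU), lobar volumetry against a lobe label map, and
    prediction of postoperative spirometry (FVC, FEV1) by the FLV
    method, the 19-segment counting method, and fixed-coefficient
    linear regression equations. Includes a synthetic thoracic CT
    phantom with analytic ground truth, a cohort simulator with the
    matching generative regression model, and an agreement-statistics
    battery (Pearson correlation, two-way absolute-agreement ICC,
    Bland-Altman limits of agreement, one-way ANOVA, OLS with p-value
    based stepwise selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
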