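Package: mammodensity
Title: Automated Mammographic Breast Density Measurement and Screening
    Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automated measurement of mammographic breast density from
    digitised film cranio-caudal mammograms. Segments the breast area while
    removing scanner borders and detached artefacts (laterality tags,
    nameplates), improves contrast within the breast, finds a per-image
    optimal intensity threshold separating dense from fatty tissue, and
    reports dense area (pixels) and percent density. Includes a synthetic
    phantom generator with ground-truth masks, a screening-cohort simulator,
    and the validation statistics used to assess density measures against
    screening outcomes: weighted population percentiles and quintile-decile
    grouping, covariate-adjusted logistic odds-ratio models, programme
    sensitivity prediction, ROC/AUC, Cuzick trend and Kruskal-Wallis tests,
    and between-measure agreement (correlation, Bland-Altman,
    cross-classification).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
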