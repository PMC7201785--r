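Package: tonguetherm
Title: Tongue Thermography Analysis for Type II Diabetes Prescreening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for prescreening type II diabetes mellitus from
    infrared tongue thermograms. Provides a synthetic cohort and thermogram
    generator (Gaussian-copula subject records plus morphology-controlled
    temperature fields), rainbow-palette rendering and inversion between
    temperature fields and RGB images, RGB color-histogram threshold
    segmentation into hot-spot and cold-spot components, gray-level
    co-occurrence matrix (GLCM) texture features, a group-statistics battery
    (Student's t, Shapiro-Wilk, Kruskal-Wallis, Pearson correlation),
    classification with linear SVM, Gaussian naive Bayes and a down-scaled
    VGG-style convolutional network under stratified 10-fold cross-validation,
    and a per-subject computer-aided diagnosis (CAD) report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
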