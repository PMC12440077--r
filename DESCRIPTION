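Package: obscdss
Title: Dose-Response Modeling and Drug Sensitivity Scoring for Brain Slice
    Culture Drug Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated analysis for ex vivo organotypic brain slice culture
    (OBSC) drug-testing assays. Measures micro-tumor bioluminescence and
    slice-viability fluorescence from multimodal plate images (well-grid
    assignment, rotated-bounding-box mask bisection, triangle thresholding),
    converts raw signals to control-normalized percent survival, fits a
    curated zoo of dose-response models (log-logistic, Weibull, exponential
    decay, Cedergreen-Ritz-Streibig and Brain-Cousens hormesis families)
    with heuristic categorization and a combined AIC/lack-of-fit selection
    criterion, and summarizes on-target tumor kill versus off-target slice
    toxicity as an eleven-window weighted Drug Sensitivity Score. Includes a
    seeded synthetic plate and dose-response generator with exhaustive
    ground truth, and Bland-Altman agreement utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
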