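Package: kinetexture
Title: Texture Analysis of Semiquantitative Kinetic Parameter Maps from
    Breast DCE-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the seven semiquantitative kinetic parameter maps
    (initial/peak enhancement, early and overall signal enhancement ratios,
    maximum slope of increase, second-phase enhancement, and signal-intensity
    slope) from nine-phase dynamic contrast-enhanced breast MRI, segments
    lesions on subtraction images by Otsu thresholding, extracts 55 texture
    features per map (histogram, gray-level co-occurrence matrix, gray-level
    run-length matrix, and two-level discrete wavelet transform families),
    and builds per-map HER2-status classifiers via a Pearson correlation
    filter, cross-validated LASSO selection, and forward stepwise logistic
    regression with Youden-threshold ROC evaluation. Includes a seeded
    two-class synthetic DCE cohort generator so the full pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
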