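Package: idcscore
Title: Automated Scoring of Soybean Iron Deficiency Chlorosis from Plot Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-processing and statistical-learning pipeline for automated
    scoring of iron deficiency chlorosis (IDC) severity in soybean field plots
    from overhead RGB images. Plants are segmented from soil by an HSV hue
    window, isolated noise is removed by morphological opening, weeds are
    excluded by retaining only plant pixels connected to the detected crop
    lines, and six colour features (plant pixel count and fraction plus five
    hue-class fractions) are extracted per plot. Linear discriminant analysis
    and support-vector-regression models map the features to 1-9 IDC severity
    scores and are evaluated with exact and within-one-point accuracy on 9x9
    confusion matrices. A synthetic-scene generator with known ground truth
    supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    igraph,
    MASS,
    e1071,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Classification, Visualization
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
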