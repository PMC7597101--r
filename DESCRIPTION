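Package: hemosmear
Title: Blood Smear Image Analysis for Red Blood Cell Morphology Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for classifying red blood cells (RBCs) in
    stained light-microscopy blood smears into size (microcytic, normocytic,
    macrocytic) and chromicity (hypochromic, normochromic, hyperchromic)
    classes. Implements green-channel preprocessing with balance contrast
    enhancement (BCET) and mean-step intensity quantization, two-step
    binarization with XOR-based white-blood-cell removal, per-cell extraction
    of a 52-dimensional feature vector (geometric shape descriptors, RGB
    intensity statistics, angle-averaged gray-level co-occurrence and
    run-length matrix features, and a 12-filter Gabor bank), adaptive
    synthetic oversampling (ADASYN) for class balance, locality sensitive
    discriminant analysis (LSDA) for dimensionality reduction, and a soft
    voting ensemble of a random forest and a multilayer perceptron. Ships a
    synthetic blood-smear generator with pixel-level ground truth so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    randomForest,
    nnet,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    cluster,
    tiff,
    withr
Config/testthat/edition: 3
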