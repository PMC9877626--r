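Package: weedseg
Title: Local-Variance Background Suppression and ECA-DenseNet Classification
    for Weed Seedling Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for separating green seedlings from cluttered field
    backgrounds and classifying them. Implements an excess-green (2G-R-B)
    vegetation index, a 3x3 local-variance texture map with non-linear
    normalization and exponential gray-level enhancement, Otsu binarization
    with morphological cleanup, dataset augmentation and splitting, a
    synthetic fixture generator with ground-truth masks, and a densely
    connected convolutional classifier with efficient channel attention
    (ECA) trained by a compact self-contained engine suitable for
    desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
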