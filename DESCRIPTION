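Package: mammoquant
Title: Quantitative Morphometry and Screen Statistics for Mammary Gland Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantification procedures used in
    studies of pubertal mammary gland morphogenesis: whole-mount epithelial-tree
    segmentation (PCA grayscale, CLAHE, wide-Gaussian background subtraction, Otsu
    binarization) and morphometry (area via concave boundary hulls, ductal extension,
    skeleton branch points, Dirichlet tessellation of branch territories, signed
    lymph-node distance); organoid/cyst protrusion quantification (compartmentalized
    fluorescence ratios for localized-translation assays, protrusion lifetime and
    geodesic length tracking); and downstream label-free proteomic screen statistics
    (half-minimum imputation, group-zero filtering, EIC normalization, Welch tests with
    q-values and log2-ratio sentinels, correlation clustering, random-forest stage
    classification, and the standard group-comparison tests). Synthetic-data generators
    with exact ground truth make every stage testable without animal images or
    deposited mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    randomForest,
    ape,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
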