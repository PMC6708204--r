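Package: aslic
Title: Adaptive Superpixel Segmentation of Glioma in T2-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic 2D glioma segmentation for T2-weighted MRI slices built
    on adaptive superpixels. Implements SLIC and SLIC0 superpixel generation
    with connectivity enforcement, an adaptive predictor of the optimal
    superpixel count driven by hemispheric-asymmetry descriptors (tumor area
    ratio and tumor boundary complexity) and a random-forest regressor, a
    69-dimensional per-superpixel feature descriptor (intensity statistics,
    Haralick textures on gray-level, gradient and curvature co-occurrence
    matrices, mean curvature, and box-counting fractal features over
    multi-level Otsu channels), SVM classification of superpixels into tumor
    and non-tumor, segmentation quality metrics (Dice, Hausdorff distance,
    sensitivity, specificity), and a synthetic head-phantom generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    tiff,
    randomForest,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
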