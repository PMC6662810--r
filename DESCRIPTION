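Package: trabtex
Title: Trabecular Bone Texture and Shape Analysis with Dispersion-Penalized Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognition pipeline for blurry low-magnification trabecular bone
    images. Computes gray-level co-occurrence (GLCM) and run-length (GLRLM)
    texture parameters in the four canonical directions, fuses direction-weighted
    texture with dimensionless shape ratios and Hu invariant moments, selects
    features with an intra-class-dispersion convex optimization model solved by
    iterative soft thresholding (ISTA), and evaluates two-class discrimination
    (sham-operated versus ovariectomized) with a linear support vector machine
    under leave-one-out cross-validation. Includes a synthetic trabecular image
    generator so the full pipeline can be exercised without the original
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    glmnet,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
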