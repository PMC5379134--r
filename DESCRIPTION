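Package: fundusMA
Title: Microaneurysm Detection in Color Fundus Images by Multifeature
    Fusion Dictionary Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects microaneurysms, the earliest lesion of diabetic
    retinopathy, in color fundus photographs. Candidates are extracted by
    multiscale Gaussian correlation filtering with adaptive-threshold
    region growing; candidate patches are described by eight image
    features, fused by a Fisher-criterion projection, and classified
    MA/non-MA by accumulated sparse-reconstruction error against
    per-class K-SVD subdictionaries. Includes FROC evaluation utilities
    and a synthetic-fundus generator so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr, MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
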