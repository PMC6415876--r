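Package: spermfx
Title: Desk-Scale Automated Semen Analysis and Method-Comparison Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for automated sperm-function testing at desk scale:
    motile-sperm counting from short microscopy videos via per-pixel
    mixture-of-Gaussians background subtraction with size gating,
    hyaluronan binding assay (HBA) scoring from paired videos of
    hyaluronic-acid-coated and uncoated regions, sperm chromatin
    dispersion (halo) DNA-fragmentation scoring by adaptive thresholding
    and head-area classification, eosin-nigrosin viability percentages,
    and the full method-comparison statistics used to validate such
    devices (least-squares and Passing-Bablok regression with cusum
    linearity test, Bland-Altman limits of agreement, exact binomial
    diagnostic confidence intervals, ROC AUC with DeLong variance).
    Includes seeded synthetic-scene generators with machine-readable
    ground truth for benchmarking every detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    jpeg,
    png,
    readxl,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
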