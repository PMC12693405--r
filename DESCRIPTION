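Package: podosem
Title: Podocyte Ultrastructure Morphometry from Scanning Electron Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies podocyte injury from calibrated scanning electron
    microscopy (SEM) images of the glomerular filtration surface. Implements
    three morphometric read-outs: slit-diaphragm (SD) fractional area by
    automatic Yen thresholding, SD fractional area by Steger curvilinear
    ridge detection, and foot-process width from intensity line profiles.
    Includes a synthetic SEM image simulator with exact ground truth for
    validation, and a diagnostic-statistics layer (group summaries, Hedges'
    g, ROC/Youden analysis, Wilson intervals, correlation, regression, and
    Bland-Altman agreement) for cohort-level evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
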