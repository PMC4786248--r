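Package: ptxcad
Title: Automated Pneumothorax Detection on Lung Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided detection of pneumothorax on thoracic ultrasound.
    Implements a B-mode pipeline (rib-shadow localization, intercostal-space
    and pleural-line detection, pleural-sliding motion estimation by
    normalized cross-correlation, sub-pleural reverberation-artifact
    detection, three-way positive/negative/indeterminate calls) and an
    M-mode pipeline (most-hyperechoic-line detection and seashore versus
    stratosphere texture classification). Ships a seeded synthetic
    speckle-phantom generator producing labeled B-mode cine clips and M-mode
    images with full ground truth, plus diagnostic-accuracy machinery:
    expert-panel adjudication with image-quality gating, confusion matrices,
    exact (Clopper-Pearson) confidence intervals, Cohen's kappa, and
    stratified accuracy reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
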