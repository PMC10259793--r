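Package: hyphometry
Title: Morphometry and Fluorescence Localization Analysis for Budding
    Bacterial Hyphae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative image analysis for budding bacteria that
    reproduce through thin polar hyphae, such as Rhodomicrobium and other
    Hyphomicrobiaceae. Implements the hyphal deformity score (the mean of
    the sines of all kink angles along a hypha, including the angle at
    which the hypha emerges from the mother cell), hyphal length
    measurement, skeleton-based extraction of cell geometry from labelled
    masks, demograph construction of per-cell fluorescence profiles,
    peak-signal-to-hyphal-tip distance analysis, and nonparametric group
    comparisons with D'Agostino-Pearson normality testing. A fully
    ground-truthed synthetic micrograph generator allows every stage of
    the pipeline to be validated without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
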