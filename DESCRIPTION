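Package: chamberflow
Title: Quantification of Flow-Chamber Cell Adhesion Assays by Temporal Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying leukocyte adhesion and rolling in
    parallel-plate flow-chamber time-lapse microscopy. Implements the
    projection-based workflow used for phase-bright monocytes on a dark
    background: a single-frame snapshot counts all substrate-interacting
    cells, a temporal minimum-intensity projection isolates cells that remain
    stationary for the whole acquisition window (firm adhesion), rolling cells
    are obtained by subtraction, and a temporal maximum-intensity projection
    turns each rolling cell into an elongated streak whose length divided by
    the acquisition time gives its average rolling velocity. Includes a
    synthetic time-lapse generator with full ground truth for validation,
    count-to-density normalization, and donor-level group statistics
    (normality-gated two-group tests, two-way factorial ANOVA, stimulation
    response ratios, and 2^-ddCt expression fold changes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    car,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
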