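Package: luxdisk
Title: Bioluminescence Quantification for Filter-Membrane Whole-Cell Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies bioluminescent whole-cell biosensor signals recorded
    with consumer smartphone cameras or ultra-low-light CMOS sensors from
    bacteria immobilized on filter-membrane disks. Implements the low-light
    image chain (frame stacking by averaging, green/blue channel merging,
    circular disk photometry with robust background subtraction), kinetic
    peak-time and measurement-window selection, induction-factor and
    signal-to-noise dose-response statistics with one-way ANOVA and Fisher's
    LSD letters, and the temperature-calibrated dark-background pipeline for
    multi-channel CMOS record streams. A forward simulator generates kinetic
    traces, smartphone frame stacks and CMOS streams with known ground truth
    so every stage of the analysis is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
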