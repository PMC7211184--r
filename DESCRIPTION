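Package: nanowellr
Title: Quantification of Multiplexed miRNA Assays on Nanoliter Well Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for spatially resolved, multiplexed miRNA
    measurements made with nanoliter well arrays sealed against tissue
    sections. Each ~3.5 nL well carries a small grid of hydrogel posts, one
    probe species per post; the mean fluorescence of a post is the raw
    measurement. The package provides the array design calculator (well
    counts, volumes, post packing, detectability), a ground-truthed
    synthetic image generator, the image pipeline (dust-artifact removal by
    connected components, two-anchor grid registration, post mean-intensity
    extraction, central window selection), signal quantification
    (negative-control subtraction, calibration curves, limit of detection,
    fold-change utilities), quality control and statistics (missing-post
    filtering, one-sided Grubbs outlier removal, Tukey HSD region
    comparisons, coefficients of variation), and spatial mapping of amounts
    onto the well lattice with region summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mgcv,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
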