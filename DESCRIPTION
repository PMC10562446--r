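Package: seqifr
Title: Simulation, Assembly and Quality Control for Sequential
    Immunofluorescence (seqIF) Imaging Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cyclic (sequential) immunofluorescence imaging:
    a synthetic-acquisition generator that emulates multi-cycle tiled
    fluorescence scans of a cell phantom with ground truth, readers and
    writers for tiled acquisitions and multi-layer OME-TIFF stacks,
    per-channel flat-field (vignetting) correction, mosaic stitching with
    DAPI-based rigid cross-cycle registration and autofluorescence
    subtraction, and the quality-control statistics used to characterize
    such assays: Otsu-threshold signal segmentation, signal-to-background
    ratios, antibody elution efficiency, epitope-stability curves,
    repeatability coefficients of variation, and signal-uniformity
    profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
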