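Package: fiberdens
Title: Automated Quantification of Immunostained Fiber Density with
    Planned Orthogonal Contrast Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the relative volume occupied by immunostained
    (e.g. DAB-labelled catecholaminergic) fibers in calibrated brightfield
    micrograph regions of interest. Detection combines the RGB channels into
    a stain-contrast plane, denoises it with a disk median filter, isolates
    high spatial frequencies by subtracting a Gaussian-smoothed copy,
    removes large stain artifacts by connected-component area filtering,
    and applies a fixed threshold; a second pass at a coarser Gaussian
    scale yields a detection ratio used to reject out-of-focus images.
    Includes a seeded generator of ground-truth-bearing synthetic
    micrographs and factorial behavioral datasets, and a planned
    between-by-within orthogonal contrast engine with simple-effects
    decomposition controlling the per-contrast error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
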