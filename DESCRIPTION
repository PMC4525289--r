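Package: knobtools
Title: Quantitative Analysis of Condensed Chromatin Knobs in Fission Yeast
    Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying chromatin condensation in super-resolution
    (3D structured-illumination) images of Schizosaccharomyces pombe nuclei,
    and for the companion one-colour microarray expression analysis. Provides
    flexible iterative (isodata) thresholding, seven-parameter chromatic
    channel registration (translation, z rotation, per-axis magnification),
    3D nucleus segmentation with cross-channel object grouping, a
    variance-based DAPI-overlap statistic computed on zero-padded normalized
    images, automated calling of condensed chromatin bodies ("knobs") with
    frequency and locus-proximity statistics, and a microarray chain with
    75-percentile normalization and paralog cross-hybridization correction
    via mismatch probes. Synthetic image and spot-table generators with
    ground truth make every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
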