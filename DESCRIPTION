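Package: gstopo
Title: Static and Dynamic Global-Signal Topography for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes static and sliding-window dynamic global-signal
    topography (GST) maps from 4D resting-state BOLD runs: gray-matter
    global signal extraction, voxelwise Pearson correlation with Fisher
    r-to-z transform, windowed z-series with SD/mean/CV summary maps,
    temporal preprocessing (volume discard, polynomial despiking,
    Friston-24 plus tissue nuisance regression, frequency-domain
    band-pass, Gaussian smoothing, motion QC), three-group voxelwise
    ANOVA with cluster-extent reporting in MNI coordinates, ROI-level
    group ordering and behavior correlations, and a synthetic
    three-group cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    signal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
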