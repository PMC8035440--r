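Package: fcdensity
Title: Binarized Functional Connectivity Density Mapping for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for voxel-wise binarized functional
    connectivity density (FCD) analysis of resting-state BOLD fMRI in a
    two-group design. Implements temporal preprocessing (initial volume
    dropping, motion-based subject exclusion, Friston-24 plus
    global/white-matter/CSF nuisance regression, linear detrending and
    0.01-0.1 Hz bandpass filtering), local and long-range FCD mapping by
    thresholded-correlation graph degree split at a 6 mm sphere, whole-brain
    normalization, Gaussian smoothing, group t-statistics with Monte-Carlo
    cluster-extent multiple-comparison correction, and ROC/AUC
    discrimination of cluster mean values with DeLong confidence intervals.
    Includes a synthetic-data generator that plants local and long-range
    connectivity structure so the whole pipeline is testable without
    acquired data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
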