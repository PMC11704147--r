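Package: octava
Title: OCT Angiography Vessel Morphometry and Longitudinal Dilation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for label-free optical coherence
    tomography angiography (OCT-A) of cortical microvessels. Computes
    flow-contrast angiograms from repeated B-scan amplitude stacks by subpixel
    DFT registration and split-spectrum amplitude decorrelation, references
    volumes to the cortical surface (de-tilt, flatten, en-face projection,
    axial binning), segments vessels and extracts a branch graph by top-hat
    enhancement, binarization and skeletonization, measures branch diameters
    as the mean full-width-at-half-maximum of Gaussian fits to perpendicular
    cross-section intensity profiles, tracks individual branches across a
    multi-timepoint sonication timeline, and reproduces the group statistics
    of a focused-ultrasound dilation study (paired t tests per animal,
    two-way ANOVA with Fisher's LSD, depth-resolved Mann-Whitney tests).
    Includes a ground-truthed synthetic 3D vascular phantom generator so the
    complete pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
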