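Package: vmtrack
Title: Evaluation Toolkit for Multi-Animal Pose Tracking with Virtual Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ground-truth-based quality assessment for multi-animal pose
    tracking. Reads and writes the tabular pose formats used by the
    DeepLabCut ecosystem (single-animal flat and multi-animal nested CSV
    headers), pairs predicted identities with ground-truth identities by
    minimum-cost Hungarian assignment, classifies every keypoint into a
    match / false-negative / false-positive taxonomy with identity-switch
    detection, evaluates centroid and virtual-marker accuracy, computes
    collective-behavior metrics (body-axis spacing variance, schooling
    cosine similarity, standardized-pose RMSD, stray-keypoint overlap),
    and provides cleaning and marker-rendering utilities plus a synthetic
    multi-animal trajectory simulator with a fully logged error model for
    testing the entire pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
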