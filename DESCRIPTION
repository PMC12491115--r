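Package: odontomatch
Title: Segmentation and Registration of 3D Dental Scans for Forensic
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing antemortem and postmortem 3D dental surface
    scans in forensic identification workflows. Implements trimmed
    iterative-closest-point (ICP) rigid registration with root-mean-square
    (RMS) deviation reporting, five soft-tissue segmentation strategies for
    full-arch scans (no segmentation, semi-automatic and manual gingival
    reduction, individual planar slicing, and a joint planar slice applied to
    two already-superimposed scans followed by re-registration), a synthetic
    dentition generator producing labelled arch meshes with ground-truth
    transforms, a study pipeline enumerating matching and non-matching
    comparison designs, and statistics for fitting an RMS match/non-match
    decision threshold (midpoint and logistic modes, Box-Cox diagnostics,
    pairwise method contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
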