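Package: mfoct
Title: Multi-Functional OCT Analysis of Layered Cranial Tissue
Version: 0.1.0
Authors@R: person("OCT", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for polarization-sensitive optical coherence tomography
    (PS-OCT) and OCT angiography (OCTA) of layered cranial anatomy such as the
    adult zebrafish head. Provides a synthetic polarization-resolved tomogram
    phantom of a skin/skull/brain cranium with ground truth; intensity,
    accumulative retardation and degree-of-polarization-uniformity (DOPU)
    contrast volumes; split-spectrum amplitude-decorrelation angiography
    (SSADA); DOPU-intensity threshold-mask organ segmentation with spline
    boundary smoothing; layer-resolved en-face renderings; transcranial-channel
    detection with cranial-suture co-localization; and vessel-density metrics
    for monitoring traumatic brain injury revascularization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
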