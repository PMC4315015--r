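Package: subnetica
Title: Multi-Order Group ICA Subnetwork Analysis of Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Group spatial independent component analysis of multi-subject
    resting-state fMRI at low and high model orders, with dual regression,
    automatic spatio-temporal labeling of high-dimensional subnetworks
    against low-dimensional reference networks (Dice overlap plus
    across-subject temporal correlation), and group comparison of network
    time-series amplitude, full-correlation network matrices (Fisher z),
    and voxelwise spatial maps via permutation max-statistic and
    max-cluster-size family-wise error control. Includes a synthetic
    multi-subject BOLD generator with planted hierarchical networks and
    group effects so the whole pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
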