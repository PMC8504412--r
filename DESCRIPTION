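Package: cerebropwv
Title: Global Intracranial Pulse Wave Velocity from 4D Flow MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates a single global intracranial pulse wave velocity (PWV)
    from cardiac-gated 4D flow MRI. Builds a complex-difference angiogram from
    magnitude and three-directional velocity volumes, enhances vessels with a
    multiscale Hessian tubular filter, skeletonizes the vascular mask into a
    branch-labeled centerline tree, extracts normalized time-resolved
    through-plane velocity waveforms at every arterial cross-section, assigns
    each cross-section a vascular path distance from the arterial root, and
    jointly fits the PWV together with a shared velocity waveform by weighted
    maximum likelihood. Includes a digital flow phantom (tabular waveform sets
    and full 4D branching-tube volumes with known ground truth) so every stage
    is testable without scan data, plus cohort comparison utilities and
    split-half consistency checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
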