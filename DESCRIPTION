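Package: petfcs
Title: PET-FCS Quenching Kinetics and MD Trajectory Dynamics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis protocol for comparing peptide end-to-end quenching
    dynamics between molecular-dynamics trajectories and photoinduced
    electron transfer fluorescence correlation spectroscopy (PET-FCS)
    measurements. Provides exact two-state (telegraph) and confocal
    photon-stream simulators with known ground truth, direct and
    multiple-tau photon correlators with segment-based uncertainties, the
    composite FCS model (antibunching, triplet, diffusion and dynamic
    quenching terms) with weighted nonlinear least-squares fitting and
    model comparison, conversion between relaxation amplitudes/times and
    microscopic contact formation/dissociation rates, and MD trajectory
    post-processing: Kabsch-superposed RMSD, single-linkage conformational
    clustering, end-to-end distance regime assignment with transition-rate
    statistics, and distance-criterion quenching-state classification with
    its autocorrelation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    igraph,
    withr
Config/testthat/edition: 3
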