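Package: lrpddm
Title: Decision-Threshold Analysis with Drift-Diffusion Fits and Lateralized
    Readiness Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the neural implementation of decision
    thresholds in two-alternative forced-choice tasks. Provides a pure
    drift-diffusion model (DDM) engine with Wiener first-passage densities,
    Euler-Maruyama trial simulation and quantile-multinomial maximum-likelihood
    fitting with parameter sharing across conditions; a three-layer
    accumulator/threshold/response network with bistable switch units and its
    simulated lateralized-readiness-potential (LRP) predictions; an LRP
    measurement pipeline (low-pass filtering, artifact rejection, C3/C4
    difference waves, 1-degree-of-freedom onset regression, peak and
    area-between-curves measures, neural non-decision time); a synthetic
    behavioral and EEG data generator with known ground truth; and the
    cross-subject statistics linking LRP measures to DDM parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
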