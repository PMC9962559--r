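Package: oxirelax
Title: LF-NMR Relaxometry Pipeline for Edible-Oil Oxidation Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, processing and machine-learning classification of
    low-field NMR transverse-relaxation (CPMG) measurements of edible oils.
    Generates class-conditional multi-exponential T2 decay curves, pulsed-field
    gradient spin-echo (PFGSE) attenuation series and companion oxidation
    chemistry (peroxide value, p-anisidine value, TOTOX, self-diffusion
    coefficient); reconstructs T2 spectra by L1/L2-regularized inverse Laplace
    transform; labels samples by diffusion/peroxide criteria; trains a 1D
    dilated convolutional network that classifies raw relaxation curves into
    three ordinal oxidation classes; and evaluates per-class precision, recall
    and F1 across repeated training sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
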