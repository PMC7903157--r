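Package: stopvar
Title: Behavioral and BOLD Variability in Stop-Signal Response Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of intra-individual variability in
    response inhibition. Simulates staircase-tracked stop-signal task
    sessions and event-related BOLD runs with known ground truth; estimates
    stop-signal reaction time (SSRT) by the horse-race integration method;
    fits a hierarchical Bayesian ex-Gaussian race model of the SSRT
    distribution (mu, sigma, tau and trigger-failure probability) by
    adaptive Metropolis-within-Gibbs sampling; quantifies trial-by-trial
    BOLD variability as the difference of residuals (DoR) between a
    condition-averaged and a trial-wise general linear model; and links the
    two with ROI extraction, ANOVAs, voxel-wise group maps, Pearson and
    partial correlations, Fisher r-to-z comparisons and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    RNifti,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
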