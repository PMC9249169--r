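Package: scLatentCor
Title: Noise-Aware Latent Correlation for Single-Cell Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates the latent correlation between two molecular layers
    (e.g. gene expression and promoter DNA methylation, or expression and
    chromatin accessibility) per genomic feature across single cells.
    A Bayesian hierarchical model couples a zero-inflated Poisson-lognormal
    likelihood for expression counts with a binomial-probit likelihood for
    methylation or accessibility calls through a bivariate Gaussian latent
    state. Per-feature posteriors are sampled with a No-U-Turn Hamiltonian
    sampler; significance calls use tail posterior probabilities with an
    expected-false-discovery-rate calibrated threshold and negative-control
    calibration of the minimum correlation of interest. Includes frequentist
    Pearson/Spearman baselines with Benjamini-Hochberg control, deviance
    information criterion comparison of zero-inflated versus plain Poisson
    likelihoods, a synthetic data generator, window-based feature
    aggregation, quality-control filters, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite,
    parallel,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
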