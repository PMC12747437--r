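Package: lear
Title: Localization-Error Reduction for Chromatin Tracing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of multiplexed DNA-FISH (chromatin tracing) trace
    tables to reduce localization error without additional experiments. Given an
    estimate of the per-locus localization error, the variance of the pairwise
    displacement between every pair of imaged loci is driven towards its
    error-free "goal variance" by a stochastic-descent likelihood maximization,
    yielding adjusted coordinates. Includes estimation of localization error
    from repeat-imaged loci, a worst-case error bound, off-target and
    detection-efficiency filtering, Gaussian-chain simulators for validation,
    and pairwise / multi-way contact-frequency analysis with independence
    baselines.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
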