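Package: sfratios
Title: Distribution of Fitness Effects from Site Frequency Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the distribution of fitness effects (DFE) of new
    mutations and the selected-to-neutral mutation-rate ratio from the
    per-bin ratios of a candidate-selected site frequency spectrum (SFS)
    to a matched neutral SFS. Per-bin counts are modelled as Poisson
    random fields; the ratio likelihood uses a gaussian approximation to
    the ratio of two Poisson counts, which cancels shared non-selective
    distortions of the two spectra (demography, linked selection).
    Includes inverted lognormal, inverted gamma, normal and fixed-effect
    DFE families with an optional point mass at zero, likelihood-ratio
    tests for selection, profile-likelihood confidence intervals, AIC
    model comparison, a Poisson random field simulator with power, ROC
    and null-calibration harnesses, and construction of mutational-
    context-matched neutral control SNP sets from VCF input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    vcfR,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
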