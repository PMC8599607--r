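Package: rhesusclocks
Title: Cross-Species DNA Methylation Clocks and Age EWAS for Primates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates elastic-net epigenetic clocks for rhesus
    macaque and dual-species (human-macaque) designs, including relative-age
    and log-linear age transformations, unbiased leave-one-out / k-fold /
    leave-one-holdout-species cross-validation, cross-species clock transfer
    with calibration diagnostics, tissue-stratified epigenome-wide
    association screening with Stouffer meta-analysis, top-CpG selection and
    overlap (upset) analysis, region-class distributions, and hypergeometric
    transcription-factor motif enrichment. Ships a synthetic methylation-array
    generator that emulates the multi-tissue primate study design with
    planted, recoverable age signals for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
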