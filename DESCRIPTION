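Package: mrmtag
Title: Fixed-Charge Derivatization MRM Assay Design and Screening Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating targeted LC-MS/MS (multiple
    reaction monitoring, MRM) assays for peptide biomarkers derivatized with a
    fixed-charge 2,4,6-triphenylpyridinium (TPP) tag. Covers monoisotopic mass
    and m/z arithmetic for modified peptides including fixed-charge tags,
    in-silico tryptic digestion and candidate peptide selection, MRM transition
    list construction and annotation of observed transitions, synthetic MRM
    chromatogram simulation with signal-to-noise based detection and
    limit-of-detection estimation, and diagnostic screening statistics
    (sensitivity, specificity, likelihood ratios, predictive values) with
    Clopper-Pearson, log-method and logit confidence intervals, plus a seeded
    synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
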