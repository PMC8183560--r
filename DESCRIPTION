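Package: fmtengraft
Title: Coverage-Aware Engraftment Analysis for Fecal Microbiota
    Transplantation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking microbial engraftment in placebo-controlled
    fecal microbiota transplantation (FMT) trials from longitudinal 16S
    amplicon sequence variant (ASV) feature tables.  Implements per-patient
    per-ASV gain and loss scores that correct apparent presence/absence
    calls for sequencing-depth disparities via Poisson detection-limit
    probabilities, donor-anchored classification of initial alpha
    diversity, generalized UniFrac beta-diversity dynamics relative to
    donors, placebo-floored rescaling of microbial source-attribution
    proportions, clinical response and severity classification from IBS
    symptom severity scores, and differential-abundance and correlation
    screens with Benjamini-Hochberg control.  A synthetic-cohort simulator
    with planted gain, loss and transient-colonization events provides
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    optparse,
    phangorn,
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
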