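Package: clinotatr
Title: Weighted Aggregation of ClinVar Clinical Assertions for
    Reclassification Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the Clinotator method for quantitative analysis of
    ClinVar-style variation reports. Clinical assertions are weighted by
    significance type, assertion age and submitter expertise category and
    summed into a raw score (CTRS); non-parametric prediction intervals
    calibrated against two-star control distributions map the score to a
    predicted clinical significance (CTPS); and the ordinal distance between
    the ClinVar significance and the prediction yields a ranked
    reclassification recommendation (CTRR, 0-3). Reads variation records
    from a line-delimited JSON fixture format or a ClinVar variation-report
    XML subset, annotates VCF 4.3 files by rsID and alternate allele, and
    ships a command-line interface for batch runs. Includes a synthetic
    record generator for calibration experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
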