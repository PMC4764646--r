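Package: crcburden
Title: Rare-Variant Filtering, Gene-Burden Screening and Candidate-Gene
    Triage for Case-Control Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a germline rare-variant discovery-and-triage
    analysis for case-control exome cohorts: a call-level filter cascade
    (read-level quality, reference-panel minor allele frequency,
    loss-of-function-tolerant gene exclusion, and impact classification
    into protein-truncating and conserved-missense classes), detection of
    biallelic and recurrently affected genes, a per-gene chi-square
    goodness-of-fit burden screen with Benjamini-Hochberg correction,
    Fisher's exact confirmation against a second control panel, and an
    ordered four-step candidate-gene evidence triage. A synthetic cohort
    generator with known per-gene truth makes the whole pipeline testable
    without external data and supports type-I error and power estimation
    for the burden screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
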