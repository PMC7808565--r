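Package: cnafid
Title: Copy-Number Fidelity Analysis for Patient-Derived Xenograft Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies conservation of somatic copy-number alteration (CNA)
    profiles between patient tumors and patient-derived xenografts across
    engraftment, passaging and lineage splits. Provides segment-level input
    handling, profile filtering and median centering, fixed-width window
    binning, conservative gene-level copy-number assignment, pairwise
    concordance via improved linear regression with studentized-residual
    outlier removal, residual-based altered-gene calling, model-based
    recurrence frequencies, gene-set proportion tests, a CN-drug association
    screen, expression-based CNA inference (e-karyotyping preprocessing plus a
    penalized piecewise-constant-fit segmenter), simplified cohort G scores
    with rescaling and delta-G shift analysis, preranked gene-set enrichment
    with a leading-edge significant-gene filter, and a ground-truthed
    simulator of PDX lineage cohorts for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
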