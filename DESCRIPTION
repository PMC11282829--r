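Package: gpcrhunt
Title: Cross-Cohort Screening of Overexpressed GPCRs in Bulk RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies G-protein coupled receptors (GPCRs) that are candidate
    cell-surface targets for ligand-decorated nanomedicines from multiple
    independent bulk RNA-seq cohorts of high-grade serous ovarian cancer.
    Implements from first principles counts-per-million, trimmed-mean-of-M-values
    (TMM) scaling factors and RPKM quantification; selects a housekeeping
    reference gene by coefficient of variation; calls expressed GPCRs relative to
    the reference, ranks them by cross-cohort frequency and retains those
    overexpressed versus a healthy-tissue baseline; clusters samples on the final
    panel; and quantifies validation qPCR data via delta-Ct fold changes. A
    seeded negative-binomial multi-cohort simulator makes the whole cascade
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
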