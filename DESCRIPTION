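Package: ldsig
Title: Low-Dose Radiation Expression Signatures and Breast-Cancer Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking strain-differential and low-dose-radiation
    responsive mouse transcription to human breast-cancer outcomes.
    Implements graded fold-change/p-value gene listing, cross-tissue
    "systemic" signature derivation, mouse-to-human ortholog mapping,
    signature sum-scores with median-split Kaplan-Meier and log-rank
    survival association, cancer-outcome-associated (COA) gene refinement,
    cross-species direction concordance, dose-response nonlinearity
    classification, and micronucleus assay statistics with Monte-Carlo
    Dunnett adjustment. Ships a seeded synthetic-data generator that
    emulates the two-strain, two-tissue, sham/low/high-dose study design
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    multcomp,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
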