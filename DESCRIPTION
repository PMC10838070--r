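Package: taxcv
Title: Cross-Validation of DNA-Barcode Reference Databases for BLAST-Based
    Taxonomic Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate how reliably a DNA-barcode reference database
    (e.g. ITS2 or rbcL) identifies taxa by sequence similarity. Implements
    four assignment strategies built on the top BLAST hits (TopHit,
    TopHitPlus, TopN, TopNPlus) with per-rank identity and consensus scores,
    leaked and k-fold cross-validation designs over general or
    primer-restricted regions and local or world database scopes,
    multi-class accuracy/precision/recall/F metrics, binomial GLMs and
    Gini classification trees (one-standard-error pruned) to calibrate
    identity/consensus thresholds, and declarative rule cascades
    (Local-then-World) to discard unreliable assignments. A seeded
    hierarchical sequence simulator generates self-contained benchmark
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
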