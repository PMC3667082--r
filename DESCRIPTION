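Package: gbmsig
Title: Gene-Signature Concordance Analysis for Glioblastoma Subtypes, EMT
    and CD133
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving fold-change gene signatures from log2
    expression matrices and testing their concordance with background-
    harmonized two-sided Fisher exact tests.  Implements the analysis
    pipeline linking glioblastoma (GBM) molecular subtypes, an
    epithelial-to-mesenchymal transition (EMT) core signature and
    CD133-sorted expression signatures: probe-to-gene collapsing,
    signature derivation (group versus reference, subtype versus rest,
    paired sorted fractions with multi-pair consensus), overlap testing
    with expected-overlap and enrichment/depletion calls, consensus
    k-means subtype discovery with a consensus-matrix quality factor,
    Pearson correlation profiling against EMT-inducer profiles, and a
    three-way discordance reconciliation.  A synthetic-study generator
    with planted signatures and known correlation structure makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
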