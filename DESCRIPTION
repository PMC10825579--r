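Package: vhhtrack
Title: Tracking VHH Antibody Repertoire Evolution over an Immunization
    Time Course
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of camelid heavy-chain antibody (VHH) repertoires
    sequenced at multiple timepoints of an immunization. Provides
    frequency-driven amplicon error cleanup, chronological unique-sequence
    tables with S#/L# identifiers, germline V/J assignment by local
    alignment with Karlin-Altschul bit scores, clonal cluster isolation by
    Jukes-Cantor distance and connected components, and in-silico
    prediction of antigen-responsive clusters from bit-score trajectories
    (negative slope, germline-like intercept, weekly clone turnover). A
    repertoire simulator with full ground truth supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    igraph,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
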