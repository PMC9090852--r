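Package: triadbalance
Title: Homoeolog Triad Expression Balance in Hexaploid Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the relative expression of homoeolog gene
    triads across the A, B and D subgenomes of hexaploid wheat (Triticum
    aestivum). Parses structured wheat gene identifiers, aggregates
    transcripts-per-million (tpm) expression matrices into per-gene
    subgenome totals and relative fractions, classifies each triad into
    seven expression-balance categories by nearest centroid on the
    expression simplex, compares balance between conditions (e.g. control
    versus heat stress), computes pairwise global-alignment identity
    between homoeolog sequences, and simulates registry, expression and
    sequence data with known truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
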