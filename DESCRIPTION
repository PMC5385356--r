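Package: consmotif
Title: Codon Conservation Profiling and Linear Motif Discovery in Ortholog Sets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reference-anchored analysis of protein-coding ortholog sets:
    star codon alignment indexed on a reference (human) open reading frame,
    per-site synonymous/nonsynonymous substitution counting (Nei-Gojobori
    style pathway enumeration), a combined 0-2 conservation score joining
    residue identity with standardized dN-dS, sliding-window discovery of
    conserved linear motifs, Tamura-Nei (TN93) distances with neighbor-joining
    trees and nonparametric bootstrap supports, and cross-taxon group
    conservation categorization. Includes a codon substitution simulator with
    site-specific omega and planted invariant motif blocks so the whole
    pipeline is testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
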