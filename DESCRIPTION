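Package: funcmark
Title: Functional-Gene qPCR Marker Design and Community Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for building and exploiting a functional-gene
    qPCR marker, developed around the acdS gene of bacterial ACC deaminase
    producers. Curates a reference database by catalytic key-residue
    filtering of a protein alignment, enumerates conserved-region primer
    candidates and screens primer pairs against six design criteria
    (nearest-neighbor melting temperature, hairpin and primer-dimer
    structure, Tm balance, product size, database coverage under mismatch
    tolerance, and specificity against non-target homologs by in-silico
    PCR), fits qPCR standard curves with amplification efficiency and
    copy-number conversion, profiles amplicon communities (read filtering,
    greedy 3 percent OTU clustering, best-hit classification, alpha
    diversity, rarefaction, Bray-Curtis), and correlates functional-group
    distances with host-plant phylogenetic distances (Kimura two-parameter,
    Spearman and Mantel tests). Deterministic synthetic-data generators
    make every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    optparse,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
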