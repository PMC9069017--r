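Package: polascreen
Title: Mining and Residue-Based Classification of Family A DNA Polymerases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale, reproducible pipeline for mining Family A DNA
    polymerase (PolA) candidates from protein sequence collections.
    Candidates are validated by reference-anchored active-site residues
    (R688, D705, K758 in Escherichia coli numbering) and classified by the
    identity of the O-helix 762 position (Phe, Leu or Tyr), then passed
    through length and conserved-domain filters, greedy identity clustering
    within source-by-residue strata, seeded stratified subsampling, and a
    neighbor-joining phylogeny with residue annotation and group-monophyly
    assessment. Companion tools tabulate polymerase-helicase gene
    neighborhood associations on source contigs and compute phage
    genome-replication rates from burst size and latent period. A synthetic
    data generator with planted truth makes every stage testable without
    external downloads.
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
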