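Package: karyofam
Title: Comparative Sequence and Structure Analysis of Importin Alpha Paralog Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of small protein paralog families,
    developed around the importin alpha (karyopherin alpha, KPNA) family of
    nuclear import receptors. Implements global pairwise and simplified
    progressive protein alignment with percent-identity matrices, maximum
    likelihood evolutionary distances under Poisson, Dayhoff and JTT models,
    neighbor-joining tree inference with outgroup rooting and subfamily
    classification, domain-partitioned divergence analysis (importin beta
    binding domain versus armadillo repeats), mapping of receptor-peptide
    contact residues from a crystal structure onto a family alignment with
    conservation classification, protein molecular weight prediction, and a
    seeded simulator that evolves a paralog family along a known tree with
    per-domain rate multipliers for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
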