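Package: gammatype
Title: Structural Classification of Plant Heterotrimeric G-Protein Gamma Subunits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies plant heterotrimeric G-protein gamma (Ggamma) subunit
    protein sequences into the three structural types A, B and C from their
    C-terminal architecture: type A carries a terminal CaaX prenylation box,
    type B has a cysteine-free C-terminus, and type C carries a long
    cysteine-rich C-terminal extension. Predicts lipidation sites (the -4
    prenylation cysteine and the -6 S-acylation cysteine of dual-lipidated
    tails) and the prenyltransferase (farnesyl- versus
    geranylgeranyltransferase-I) implied by the CaaX X residue, derives
    majority-rule C-terminal consensus sequences, projects gene exon
    boundaries onto protein coordinates, detects short tandem repeats in
    cysteine-rich tails, and quantifies bootstrap bipartition support for
    type clusters on neighbor-joining trees built from the conserved central
    domain. A seeded synthetic-cohort generator with planted ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
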