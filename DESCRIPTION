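Package: cytodrift
Title: Cytoplasmic Clade Dynamics from Pool-Seq Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for tracking maternally inherited cytoplasmic lineages
    (Wolbachia clades and their linked mitochondrial haplotypes) in
    evolve-and-resequence experiments. Provides a forward simulator of
    cytoplasmic lineage dynamics with maternal transmission, imperfect
    transmission fidelity, clade-specific selection and optional cytoplasmic
    incompatibility; a Pool-Seq observation model emitting PoPoolation2
    sync-format allele counts; identification of clade-diagnostic SNPs from
    labelled haplotype panels; clade-frequency estimation as the median of
    diagnostic SNP frequencies after hypergeometric downsampling to fixed
    coverage; an exact Wright-Fisher drift null test based on transition
    matrix powers with replicate combination; selection-coefficient
    estimation by inversion of the haploid selection recursion; and
    sequencing-coverage-based infection calling and relative titer
    estimation for endosymbionts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
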