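Package: wrkycatalog
Title: Motif-Based Cataloguing of the WRKY Transcription Factor Family
    in Allohexaploid Wheat
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies WRKY transcription factor family members in an
    allohexaploid proteome by conserved-motif scanning (the WRKYGQK
    heptapeptide followed by a C2H2- or C2HC-type zinc finger), collapses
    splice isoforms, builds neighbor-joining trees with bootstrap support
    from progressive multiple alignments, infers homeologous gene groups
    across the A, B and D subgenomes, applies a chromosome-ordered
    nomenclature, classifies members into WRKY groups I, IIa-IIe and III,
    and summarises homeolog retention. Ships a seeded simulator of
    allohexaploid proteomes with planted family structure so every
    pipeline stage can be exercised without external downloads, plus qPCR
    2^-ddCt and TPM expression utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
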