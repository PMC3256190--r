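Package: barcodeval
Title: Evaluation of Multi-Locus DNA Barcoding Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate candidate DNA barcode loci and their
    combinations, developed around plastid markers (rbcL, matK and the
    trnH-psbA intergenic spacer) as used for seagrass identification.
    Implements alignment site-composition statistics (conserved, variable,
    singleton and parsimony-informative characters), uncorrected p-distance
    analysis with intra-/inter-group partitioning and barcoding-gap
    reporting, tree-based evaluation (neighbour-joining, maximum parsimony
    and maximum likelihood with nonparametric bootstrap, majority-rule
    consensus and topology comparison), character-based barcoding via
    diagnostic characteristic attributes, inverted-repeat detection in
    spacer sequences by self versus reverse-complement dynamic programming,
    in-silico PCR with degenerate primers, rank-level identification
    against a local reference library, and a multi-locus sequence
    simulator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
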