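Package: academscan
Title: Structural Annotation and Lineage Classification of Academ DNA
    Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes DNA transposons of the Academ superfamily from
    genome sequences: seeded local-alignment scanning for genomic copies,
    single-linkage clustering into families, majority-rule consensus
    reconstruction with iterative flank refinement until target site
    duplications (TSDs) are detected, terminal inverted repeat (TIR) and
    TSD boundary calling, six-frame ORF finding with DDE-transposase,
    SF2-helicase, PHD and CCHH zinc-finger motif scanning, and
    classification into the AcademH, AcademHP, AcademX and non-autonomous
    lineages. Includes a synthetic-genome simulator that plants Academ-like
    insertions of fully known structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    withr
Config/testthat/edition: 3
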