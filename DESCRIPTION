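Package: denovotrio
Title: Trio-Based De Novo Variant Discovery with Private-Variant Cohort
    Filtering
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of the whole-genome trio strategy for
    isolating causal de novo variants in an isolated case of a rare Mendelian
    disorder. Variants called in a proband are filtered against a control
    cohort (private-variant filtering), restricted to protein-changing
    consequences by a transcript-aware annotator that renders HGVS c. and p.
    notation, and verified as de novo against both parental genomes.
    Supporting components flag likely sequencing artifacts near assembly gaps,
    repeats and coverage dropouts, confirm parentage by Mendelian-error
    counting, method-of-moments identity-by-descent estimation and
    microsatellite transmission checks, and assess residue conservation in
    protein multiple alignments. A synthetic-data generator produces a
    miniature diploid genome, gene models, control cohort and trio with a
    full planted-truth manifest so the entire cascade is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
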