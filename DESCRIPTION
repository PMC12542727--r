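Package: mcasr
Title: Cataloguing Mitotic Chromosome-Associated Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies small RNAs that remain tightly and stably bound to
    mitotic chromosomes from small RNA-seq libraries prepared under multiple
    chromosome wash conditions. Aligned reads are filtered (length <= 30 nt,
    uniquely mapped), grouped into clusters by 5'-end proximity (single-linkage,
    gap < 15 nt), quantified as reads per million (RPM), and reduced to a
    high-confidence catalogue via a cumulative-read RPM cut-off and a
    cross-condition fold-change stability criterion. Surviving clusters are
    classified against miRNA, piRNA and TSS-associated RNA annotations. A
    synthetic-data generator with planted ground-truth loci makes every stage
    testable without access to deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
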