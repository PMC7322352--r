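Package: mreq
Title: Quantification and Selection of MicroRNA Response Elements from
    3'UTR RNA-Seq Read Support
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies microRNA response element (MRE) read support at
    3'UTRs from RNA-Seq alignments, normalizes the resulting counts for
    library size, 3'UTR length and GC content, selects condition-specific
    MREs by intersecting an unequal-variance pairwise multiple-comparison
    test (Dunnett's C) with a negative-binomial exact differential test,
    and decouples selected MREs into their interacting mRNA and microRNA
    sets. Includes a fully ground-truthed synthetic data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
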