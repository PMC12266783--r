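Package: methregen
Title: Methylome-Transcriptome Integration and Epigenetic Clock Analysis
    for Muscle Regeneration Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links CpG methylation to gene expression and epigenetic age in
    regenerating skeletal muscle. Provides per-probe differential
    methylation with empirical-Bayes moderated statistics and
    unwanted-variation adjustment from negative-control probes, conversion
    of differentially methylated CpGs to methylation peaks, TSS-distance
    regulatory-potential scoring integrated with differential expression by
    rank products and one-sided CDF (activating/repressive) tests,
    application and training of linear DNA-methylation age clocks with
    gold-median imputation, the study-level inferential statistics, and a
    synthetic-study generator emulating a paired contralateral-limb
    methylation array design so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
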