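Package: ntbsmap
Title: Discovery and Spatial Analysis of Internal Telomerase Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational pipeline used to
    map non-telomeric binding sites (NTBS) of the yeast telomerase catalytic
    subunit Est2 and to show that they are spatially telomere-proximal.
    Provides sliding-window ChIP-chip peak calling with a mirrored-Gaussian
    null and replicate consensus, interval-permutation enrichment statistics
    for sequence composition and feature overlap, Hi-C contact-map
    construction (in-silico restriction digestion, read-pair classification,
    proportional binning, Sinkhorn-Knopp balancing), a per-site
    telomere-proximity classifier with a Wilcoxon randomization test, qPCR
    fold-enrichment and telomere-healing quantification, and a seeded
    synthetic-data generator that emulates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
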