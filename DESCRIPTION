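Package: bgrd
Title: Broad Genic Repression Domain Analysis for H3K27me3 ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies broad genic repression domains (BGRDs) and focal
    genic repression domains (FGRDs) from H3K27me3 ChIP-Seq peak calls and
    gene annotations. Per-gene peak width and height statistics are ranked
    and a knee-point (L-curve turning point) cutoff defines BGRD genes;
    one-tailed hypergeometric enrichment curves relate domain width to
    oncogene content. Multi-sample panels are quantile-normalized to a
    reference sample, per-gene BGRD conservation is computed, and an optimal
    reference panel is selected by forward search on enrichment P values.
    Shortened and lengthened BGRDs are called between cancer and normal
    samples, pairwise and cohort-level, with a label-shuffle null, and a
    filter cascade nominates candidate tumor-promoting genes and lncRNAs.
    A synthetic-data generator with planted domain structure supports
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ChIPSeq, Epigenetics, GeneRegulation, PeakDetection
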