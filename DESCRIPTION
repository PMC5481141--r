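Package: medipdyn
Title: Developmental Methylome Dynamics from MeDIP-Seq Fragment Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of genome-wide DNA methylation dynamics across
    developmental stages from MeDIP-seq enrichment counts, as applied to
    mosaic invertebrate methylomes such as the oyster. Provides counts-per-
    million quantification and replicate-based methylation calls, a sliding-
    window differentially methylated region (DMR) caller based on an exact
    conditional negative-binomial test, feature annotation and transposable-
    element class contingency analysis, stage-kinetics selection and K-means
    clustering, methylation-expression linkage (decile trends, kinetics
    correlation, DMR proximity), Fisher exact term enrichment, and a
    negative-binomial synthetic-data generator that emulates the study
    design (eight stages, two to three replicates, planted DMRs at the
    cleavage and metamorphosis steps) so the whole pipeline is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    edgeR,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
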