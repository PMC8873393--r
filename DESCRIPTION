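Package: uvtx
Title: Chromatin and Cytoplasmic Transcriptome Dynamics after UV Irradiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of fractionated (chromatin-associated versus cytoplasmic)
    RNA-seq time courses following UV-C irradiation, together with a mechanistic
    synthetic-data generator. The simulator places pyrimidine-dimer lesions by a
    Poisson process on the genomic template, repairs them with per-lesion
    exponential kinetics, truncates transcription elongation at the first
    unrepaired lesion beyond a promoter-proximal window, propagates nascent
    signal into cytoplasmic mRNA accumulation/decay dynamics, and samples
    negative-binomial read counts for a two-fraction, four-timepoint design.
    The analysis side provides FPKM quantification, median-of-ratios size
    factors, a chromatin-enrichment statistic, a self-contained
    negative-binomial Wald test with Benjamini-Hochberg correction, temporal
    recovery classification (recovered / not recovered / induced / unchanged),
    k-means profile clustering, sample-level PCA, gene-feature comparisons,
    and a long-noncoding-RNA / TUCP identification cascade with an ORF-based
    coding-potential heuristic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
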