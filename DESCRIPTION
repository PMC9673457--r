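Package: cftss
Title: Cell-Free DNA Nucleosome Footprint Profiling at Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers transcriptional activity from low-coverage cell-free DNA
    (cfDNA) whole-genome sequencing by profiling nucleosome-footprint coverage
    around transcription start sites (TSSs). Provides readers for fragment
    intervals (BED/BAM), TSS annotations and sample sheets; GC-bias estimation
    and fragment reweighting; strand-aware per-base TSS metaplots and
    RPKM-normalized promoter-window matrices; random pooling of low-coverage
    control samples into pseudo-samples; differential promoter-coverage calls
    between cohorts (fold-change prefilter, two-sided Wilcoxon rank-sum test,
    Benjamini-Hochberg FDR, triple-criterion calls); and downstream PCA,
    hierarchical clustering, hypergeometric gene-set over-representation and
    gene-list intersection. A seeded synthetic-data generator produces
    reference genomes with isochore-like GC structure and cfDNA fragment sets
    with nucleosome-depleted promoters, downstream phasing, GC sampling bias
    and planted case/control differences, so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    ape,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    pheatmap
Config/testthat/edition: 3
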