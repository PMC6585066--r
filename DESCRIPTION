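Package: cnvbreaks
Title: Recurrent Copy-Number Breakpoint Regions from SNP Array Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for detecting recurrent genome-reorganization sites
    from SNP-array intensity data. Per-SNP allele intensities are summed,
    referenced against an averaged panel of non-malignant samples, and
    log2-ratio tracks are partitioned into segments of constant copy number
    by circular binary segmentation with permutation significance and
    SD-based undo pruning. Segment boundaries passing a log2-difference and
    SNP-support rule are called as breakpoints, assigned to 100 kb genome
    bins, and aggregated across sample cohorts into per-bin recurrence
    counts, tumor-versus-control odds ratios with a zero-cell correction,
    and common-fragile-site overlap summaries. A synthetic-cohort generator
    with planted, group-specific breakpoint regions provides ground truth
    for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
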