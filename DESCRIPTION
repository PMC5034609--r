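Package: methdyn
Title: Differential DNA Methylation Dynamics in Brown and White Adipogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for reduced representation bisulfite
    sequencing (RRBS) differential methylation analysis of a nine-sample
    brown/white adipogenesis time course. Provides readers for
    bismark-coverage-style CpG call tables, refFlat/BED gene models and CpG
    island intervals; promoter/gene-body/CGI-band annotation; common-coverage
    filtering; per-CpG Fisher exact testing with Benjamini-Hochberg adjustment
    and promoter-level differentially methylated promoter (DMP) calling;
    cross-timepoint consistency and hypergeometric gene-family enrichment;
    promoter methylation versus expression anti-correlation; merged-CpG-region
    clustering and PCA; and a seeded beta-binomial methylome simulator with
    planted ground truth for power and error-rate evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
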