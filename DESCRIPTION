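Package: mireqtl
Title: MicroRNA Expression QTL Mapping with Weighted GBLUP Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps genetic regulators of microRNA expression from small-RNA
    sequencing counts and SNP dosages. Counts are filtered, TMM-normalized and
    voom-transformed to log-CPM with precision weights; each miRNA is fit with a
    weighted GBLUP mixed model whose random effect carries a genomic
    relationship matrix, heritability is estimated by REML and tested by
    likelihood ratio; per-SNP effects are recovered by backsolving the predicted
    breeding values into standardized association statistics with
    false-discovery-rate control; significant SNPs are assembled into eQTL
    peaks classified as local or distant regulators; conditional scans fixing a
    peak SNP estimate the proportion of expression variance it explains; and
    eQTL peaks are integrated with phenotype QTL and predicted target genes via
    interval colocalization, Kendall and Pearson correlation layers. A
    synthetic-data generator with planted genetic effects provides a
    ground-truth test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
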