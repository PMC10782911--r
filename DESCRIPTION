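Package: brooklynr
Title: Chromosome-Scale Co-Expression Analysis for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects large-scale chromosomal co-expression dysregulation in
    single-cell and single-nucleus RNA-seq data. For each of a set of standard
    marker genes spread across the genome, the package correlates raw counts
    against a search space of highly expressed genes, ranks partners by
    Bonferroni-corrected p-value, and reports the percentage of the top
    correlated genes that lie on the marker's own chromosome. Genome-wide
    'Brooklyn plots' of these percentages against cumulative genomic position,
    with per-chromosome expected-by-chance baselines, reveal cell populations
    in which unusually wide chromosomal domains are co-transcribed. Includes a
    transcriptional-burst simulator producing sparse counts with configurable
    co-activated gene blocks (and matched nulls) for validation, native h5ad
    input/output, and annotation support from TSV or GTF/GFF3.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    readr,
    rhdf5,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
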