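Package: scoval
Title: Coverage- and Allele-Based Validation of Single-Cell Copy Number Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and validation of megabase-scale somatic copy number
    variants (CNVs) in low-coverage single-cell whole-genome sequencing, aimed
    at somatic mosaicism in post-mitotic tissues such as human cortical
    neurons. Read-depth CNV candidates are obtained from variable-mappability
    binning, per-cell normalization and circular binary segmentation, with
    copy-number state cutoffs calibrated by a Gaussian mixture over segment
    medians. Heterozygous-deletion candidates are then arbitrated with phased
    loss-of-heterozygosity evidence from windows of 20-100 phased germline
    heterozygous SNPs (empirical p values against non-carrier cells and a
    naive-Bayes Gaussian classifier); homozygous-deletion candidates are
    arbitrated by a cell-versus-bulk read-depth-ratio mixture model.
    Downstream statistics include permutation-based 5 Mb hotspot/cold-spot
    detection, recurrent breakpoint-bin (CNVB) and recurrent CNV (CNVR)
    analysis with haplotype-based clonality classification, per-cell Poisson
    CNV-count modelling and karyotype clustering. A synthetic-data generator
    with known ground truth exercises the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    withr
Config/testthat/edition: 3
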