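#' Read phased heterozygous SNPs from a VCF
#'
#' Parses a VCF containing phased genotypes (`0|1` / `1|0`) with phase-set
#' (`PS`) annotations into a tibble of phased heterozygous SNPs. Each
#' phase set on a chromosome becomes one phase block; haplotype 1 / 2 are the
#' left / right alleles of the phased genotype. Positions are converted to
#' 0-based on ingest. Unphased heterozygous sites are skipped and counted.
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @param sample Sample column to use (default: first sample).
#' @return A tibble with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `block_id` (chrom:PS), `hap1_allele`, `hap2_allele` (each "ref"/"alt").
#'   Attribute `n_unphased_skipped` counts skipped het sites.
#' @export
read_phased_vcf <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_phased_vcf() requires the vcfR package")
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_all <- vcfR::extract.gt(vcf, element = "GT")
  ps_all <- suppressWarnings(vcfR::extract.gt(vcf, element = "PS"))
  if (is.null(sample)) sample <- colnames(gt_all)[1]
  gt <- unname(gt_all[, sample])
  ps <- if (is.null(ps_all)) rep(NA_character_, length(gt)) else
    unname(ps_all[, sample])
  het <- gt %in% c("0|1", "1|0", "0/1", "1/0")
  phased <- gt %in% c("0|1", "1|0") & !is.na(ps)
  n_skip <- sum(het & !phased)
  keep <- which(phased)
  out <- tibble::tibble(
    chrom = as.character(fix[keep, "CHROM"]),
    pos = as.numeric(fix[keep, "POS"]) - 1,
    ref = as.character(fix[keep, "REF"]),
    alt = as.character(fix[keep, "ALT"]),
    block_id = paste0(fix[keep, "CHROM"], ":", ps[keep]),
    hap1_allele = ifelse(gt[keep] == "0|1", "ref", "alt"),
    hap2_allele = ifelse(gt[keep] == "0|1", "alt", "ref")
  )
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "n_unphased_skipped") <- n_skip
  out
}

#' Write phased heterozygous SNPs as a VCF
#'
#' Inverse of [read_phased_vcf()]; used by the simulator to emit its phased
#' germline SNPs in standard form. Positions are written 1-based.
#'
#' @param snps Tibble as returned by [read_phased_vcf()].
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(snps, path, sample = "bulk") {
  ps <- sub("^.*:", "", snps$block_id)
  gt <- ifelse(snps$hap1_allele == "ref", "0|1", "1|0")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    paste(snps$chrom, format(snps$pos + 1, scientific = FALSE, trim = TRUE),
          ".", snps$ref, snps$alt, ".", "PASS", ".", "GT:PS",
          paste0(gt, ":", ps), sep = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a cells-by-bins count matrix from TSV
#'
#' The TSV must have a `cell_id` column followed by one column per bin, with
#' bin columns named `bin<k>` (or matching `bins$bin` if supplied).
#'
#' @param path Input TSV.
#' @param bins Optional bin table to validate against; an error names the
#'   first missing bin column.
#' @return An integer matrix, rows = cells (named), columns = bins.
#' @export
read_cell_counts <- function(path, bins = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot("cell_id" %in% names(df))
  if (!is.null(bins)) {
    want <- paste0("bin", bins$bin)
    miss <- setdiff(want, names(df))
    if (length(miss) > 0) {
      stop("count matrix is missing bin column(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    df <- df[, c("cell_id", want)]
  }
  m <- as.matrix(df[, setdiff(names(df), "cell_id")])
  rownames(m) <- df$cell_id
  storage.mode(m) <- "double"
  m
}

#' Write a cells-by-bins count matrix to TSV
#' @param counts Matrix, rows = cells (rownames = cell ids).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_cell_counts <- function(counts, path) {
  df <- tibble::as_tibble(counts, .name_repair = "minimal")
  if (is.null(colnames(counts))) {
    names(df) <- paste0("bin", seq_len(ncol(counts)))
  }
  df <- dplyr::bind_cols(tibble::tibble(cell_id = rownames(counts)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read per-cell per-SNP allele depths from TSV
#'
#' Long format: one row per (cell, SNP) with reference and alternate read
#' depths. Positions are 0-based in this file (internal convention).
#'
#' @param path Input TSV with columns `cell_id`, `chrom`, `pos`,
#'   `ref_depth`, `alt_depth`.
#' @return A tibble with those columns.
#' @export
read_allele_depths <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          cell_id = readr::col_character(),
                          chrom = readr::col_character(),
                          pos = readr::col_double(),
                          ref_depth = readr::col_integer(),
                          alt_depth = readr::col_integer()
                        ))
  need <- c("cell_id", "chrom", "pos", "ref_depth", "alt_depth")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("allele-depth TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_allele_depths
#' @param depths Tibble of allele depths.
#' @param path Output TSV.
#' @export
write_allele_depths <- function(depths, path) {
  readr::write_tsv(depths, path)
  invisible(path)
}

#' Write and read CNV calls as BED
#'
#' BED output is 0-based half-open with columns
#' `chrom, start, end, cell_id, type, median_cn, nb_posterior, empirical_p`.
#' `read_calls_bed()` restores the same tibble, so write-then-read is
#' lossless for these fields.
#'
#' @param calls Call tibble (columns above; missing statistics become `NA`).
#' @param path Output/input path.
#' @return `write_calls_bed()` returns `path` invisibly; `read_calls_bed()`
#'   a tibble.
#' @export
write_calls_bed <- function(calls, path) {
  for (col in c("median_cn", "nb_posterior", "empirical_p")) {
    if (!col %in% names(calls)) calls[[col]] <- NA_real_
  }
  df <- calls[, c("chrom", "start", "end", "cell_id", "type",
                  "median_cn", "nb_posterior", "empirical_p")]
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
read_calls_bed <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "cell_id", "type",
                  "median_cn", "nb_posterior", "empirical_p"),
    col_types = "cddccddd", na = "NA", show_col_types = FALSE
  )
}

#' Read a BED file of intervals
#'
#' Minimal BED reader for masks, blacklists, gene models and peak tracks.
#' The optional 4th column is kept as `name`; a numeric 5th column as
#' `score`.
#'
#' @param path BED path.
#' @return Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#")
  if (ncol(df) < 3) stop("BED needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df$chrom <- as.character(df$chrom)
  tibble::as_tibble(df[, seq_len(min(5, ncol(df)))])
}

#' Persist and restore a copy-number calibration as JSON
#' @param calibration A `scoval_calibration` from [fit_cutoff_gmm()].
#' @param path JSON path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` a `scoval_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "scoval_calibration")
}
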