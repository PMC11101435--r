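#' Run the full coverage + allele CNV pipeline
#'
#' Convenience wrapper chaining every stage: normalization, outlier-bin
#' masking, cell QC, segmentation, mixture calibration of copy-number
#' cutoffs, raw calling, SNP-window construction, informative-read
#' counting, empirical LOH p values, naive-Bayes classification against
#' size-matched null regions, sparse-window filtering, read-depth-ratio
#' arbitration of homozygous candidates, duplication assessment, and final
#' call assembly.
#'
#' @param counts Cells-by-bins count matrix.
#' @param bins Bin table from [make_variable_bins()].
#' @param layout A [genome_layout()].
#' @param snps Phased SNP tibble (see [read_phased_vcf()]).
#' @param depths Allele-depth tibble (see [read_allele_depths()]).
#' @param bulk Optional bulk per-bin counts (pseudo-bulk substituted and
#'   flagged when absent).
#' @param seed RNG seed for segmentation permutations and null-region
#'   placement (default 1).
#' @param cbs_nperm Permutations per segmentation split test (default
#'   1000).
#' @param candidate_p Candidate LOH p cutoff (default 0.05).
#' @param final_p Final LOH p rule (default 0.01).
#' @param posterior_cutoff Classifier / RDR posterior rule (default 0.99).
#' @param n_null_sets Size-matched null sets for classifier training
#'   (default 100).
#' @param manual_exclude Cell ids to exclude at QC with reason `MANUAL`.
#' @param calibration Optional precomputed `scoval_calibration`; fitted
#'   from the data when `NULL`.
#' @return A `scoval_result` list with elements `masked_bins`, `cn`, `qc`,
#'   `segments`, `calibration`, `raw_calls`, `snp_windows`,
#'   `window_stats`, `calls` (all stages annotated), `dup_assessment`,
#'   `final` (a `scoval_callset`), `kept_cells`.
#' @export
scoval_pipeline <- function(counts, bins, layout, snps, depths,
                            bulk = NULL, seed = 1, cbs_nperm = 1000,
                            candidate_p = 0.05, final_p = 0.01,
                            posterior_cutoff = 0.99, n_null_sets = 100,
                            manual_exclude = character(),
                            calibration = NULL) {
  set.seed(seed)
  cn0 <- normalize_cells(counts)
  masked <- detect_outlier_bins(cn0)
  cn <- normalize_cells(counts, masked)
  qc <- filter_cells(cell_qc(counts, cn, bins),
                     manual_exclude = manual_exclude)
  kept <- qc$cell_id[qc$keep]
  if (length(kept) == 0) stop("no cells pass QC")
  cnk <- cn[kept, , drop = FALSE]

  segments <- segment_cells(cnk, bins, nperm = cbs_nperm)
  if (is.null(calibration)) {
    calibration <- withCallingHandlers(
      fit_cutoff_gmm(segments$median_cn),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  raw <- call_raw_cnvs(segments, calibration, bins)

  snp_windows <- build_snp_windows(snps)
  window_stats <- count_informative_reads(depths, snp_windows,
                                          cells = kept)

  calls <- loh_pvalues(raw, window_stats, snp_windows)
  calls <- sparse_window_filter(calls, window_stats, snp_windows)

  # naive-Bayes classifier: LOH-supported candidates vs size-matched nulls
  cand <- calls[calls$type %in% c("HET_DEL", "HOM_DEL") &
                  !is.na(calls$empirical_p) &
                  calls$empirical_p < candidate_p, ]
  calls$nb_posterior <- NA_real_
  if (nrow(cand) >= 2) {
    nulls <- make_null_regions(cand, layout, n_sets = n_null_sets)
    null_stats <- region_median_stat(nulls, window_stats, snp_windows)
    clf <- fit_loh_classifier(cand$carrier_stat,
                              null_stats$stat[is.finite(null_stats$stat)])
    score <- calls$type %in% c("HET_DEL", "HOM_DEL") &
      is.finite(calls$carrier_stat)
    calls$nb_posterior[score] <- predict(clf, calls$carrier_stat[score])
  } else {
    clf <- NULL
  }
  calls$status <- ifelse(
    calls$type %in% c("HET_DEL", "HOM_DEL") &
      !is.na(calls$empirical_p) & calls$empirical_p < candidate_p,
    "CANDIDATE", calls$status
  )

  rdr <- compute_rdr(counts[kept, , drop = FALSE], bulk)
  # RDR mixture trained on LOH-validated hets + provisional homs
  het_val <- calls$type == "HET_DEL" & !is.na(calls$empirical_p) &
    calls$empirical_p < final_p & !is.na(calls$nb_posterior) &
    calls$nb_posterior > posterior_cutoff
  train_calls <- calls[het_val | calls$type == "HOM_DEL", ]
  if (any(calls$type == "HOM_DEL")) {
    arb <- withCallingHandlers(
      classify_homdels(train_calls, rdr,
                       posterior_cutoff = posterior_cutoff),
      warning = function(w) invokeRestart("muffleWarning")
    )
    hom_rows <- arb[arb$type == "HOM_DEL" | arb$status == "RECLASSIFIED", ]
    m <- match(
      paste(hom_rows$cell_id, hom_rows$chrom, hom_rows$start),
      paste(calls$cell_id, calls$chrom, calls$start)
    )
    calls$rdr_mean <- NA_real_
    calls$rdr_posterior <- NA_real_
    calls$rdr_mean[m] <- hom_rows$rdr_mean
    calls$rdr_posterior[m] <- hom_rows$rdr_posterior
    calls$type[m] <- hom_rows$type
    calls$status[m] <- hom_rows$status
  } else {
    calls$rdr_mean <- NA_real_
    calls$rdr_posterior <- NA_real_
  }

  dup <- dup_assessment(calls, window_stats, snp_windows, layout)

  final <- assemble_final_calls(calls, n_cells = length(kept),
                                final_p = final_p,
                                posterior_cutoff = posterior_cutoff)
  structure(
    list(masked_bins = masked, cn = cn, qc = qc, segments = segments,
         calibration = calibration, raw_calls = raw,
         snp_windows = snp_windows, window_stats = window_stats,
         calls = calls, loh_classifier = clf, dup_assessment = dup,
         rdr = rdr, final = final, kept_cells = kept, bins = bins,
         layout = layout),
    class = "scoval_result"
  )
}

# median pseudocount |log2| per placed region (same cell's windows)
region_median_stat <- function(regions, window_stats, snp_windows) {
  wmat <- stat_matrix(window_stats, "abs_log2_pc")
  windows <- snp_windows$windows
  stat <- vapply(seq_len(nrow(regions)), function(i) {
    wid <- windows$window_id[windows$chrom == regions$chrom[i] &
                               windows$start >= regions$start[i] &
                               windows$end <= regions$end[i]]
    if (length(wid) == 0 || !regions$cell_id[i] %in% rownames(wmat)) {
      return(NA_real_)
    }
    stats::median(wmat[regions$cell_id[i], wid], na.rm = TRUE)
  }, numeric(1))
  dplyr::mutate(regions, stat = stat)
}

# duplication assessment against size-matched euploid regions per cell
dup_assessment <- function(calls, window_stats, snp_windows, layout,
                           n_sets = 5) {
  dups <- calls[calls$type == "DUP", ]
  if (nrow(dups) == 0) {
    return(assess_duplications(numeric(0), numeric(0)))
  }
  windows <- snp_windows$windows
  smat <- stat_matrix(window_stats, "abs_log2")
  grab <- function(regions) {
    unlist(lapply(seq_len(nrow(regions)), function(i) {
      wid <- windows$window_id[windows$chrom == regions$chrom[i] &
                                 windows$start >= regions$start[i] &
                                 windows$end <= regions$end[i]]
      if (length(wid) == 0 ||
            !regions$cell_id[i] %in% rownames(smat)) return(numeric(0))
      smat[regions$cell_id[i], wid]
    }))
  }
  # euploid samples avoid all of the cell's calls
  eup <- make_null_regions(dups, layout, n_sets = n_sets, exclude = calls)
  assess_duplications(grab(dups), grab(eup))
}

#' @export
print.scoval_result <- function(x, ...) {
  g <- glance(x$final)
  cat("<scoval_result> ", length(x$kept_cells), " cells pass QC; ",
      nrow(x$raw_calls), " raw calls -> ", g$n_final,
      " final deletions in ", g$n_cnv_cells, " CNV cells (",
      g$pct_cnv_cells, "%)\n", sep = "")
  invisible(x)
}
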