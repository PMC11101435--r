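#' Normalize per-cell bin counts to copy number
#'
#' Each cell's raw bin counts are scaled so that the average copy number over
#' unmasked bins is exactly two (the expected autosomal ploidy):
#' `cn = 2 * raw / mean(raw[unmasked])`. Masked bins are excluded from the
#' mean and set to `NA` in the result.
#'
#' @param counts Numeric matrix, rows = cells (rownames = cell ids),
#'   columns = bins.
#' @param masked_bins Integer indices of masked bin columns.
#' @return Matrix of copy-number estimates, same shape as `counts`, masked
#'   columns `NA`.
#' @examples
#' normalize_cells(matrix(c(10, 10, 20, 0), 1, dimnames = list("c1", NULL)))
#' @export
normalize_cells <- function(counts, masked_bins = integer()) {
  stopifnot(is.matrix(counts))
  unmasked <- setdiff(seq_len(ncol(counts)), masked_bins)
  mns <- rowMeans(counts[, unmasked, drop = FALSE])
  if (any(mns == 0)) {
    stop("cell(s) with zero reads in unmasked bins: ",
         paste(utils::head(rownames(counts)[mns == 0], 5), collapse = ", "))
  }
  cn <- 2 * counts / mns
  if (length(masked_bins) > 0) cn[, masked_bins] <- NA_real_
  cn
}

#' Flag outlier bins by Tukey's rule on cross-cell median copy number
#'
#' Bins that are systematically over- or under-amplified across the whole
#' population (WGA artifacts, residual mappability problems) are detected
#' from the per-bin median copy number over all cells: a bin is flagged when
#' its median exceeds `Q3 + k*IQR` or falls below `Q1 - k*IQR` of the
#' distribution of the medians. Flagged bins should be masked; neighbouring
#' bins keep their own coordinates.
#'
#' @param cn Copy-number matrix (cells x bins) from [normalize_cells()].
#' @param k Tukey fence multiplier (default 1.5).
#' @return Integer vector of flagged bin indices.
#' @export
detect_outlier_bins <- function(cn, k = 1.5) {
  stopifnot(ncol(cn) >= 4)
  med <- apply(cn, 2, stats::median, na.rm = TRUE)
  q <- stats::quantile(med, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  which(med > q[2] + k * iqr | med < q[1] - k * iqr)
}

#' Per-cell quality metrics
#'
#' Computes, per cell: total reads, the median absolute deviation (MAD) of
#' bin copy numbers (a WGA-noise metric), and the maximum fraction of reads
#' aligned to a single chromosome.
#'
#' @param counts Raw count matrix (cells x bins).
#' @param cn Copy-number matrix from [normalize_cells()].
#' @param bins Bin table from [make_variable_bins()].
#' @return Tibble with `cell_id`, `total_reads`, `mad`,
#'   `chrom_read_fraction`.
#' @export
cell_qc <- function(counts, cn, bins) {
  stopifnot(ncol(counts) == nrow(bins))
  total <- rowSums(counts)
  mad_cn <- apply(cn, 1, function(v) {
    v <- v[is.finite(v)]
    stats::median(abs(v - stats::median(v)))
  })
  chrom_totals <- t(rowsum(t(counts), group = bins$chrom))
  frac <- apply(chrom_totals / total, 1, max)
  tibble::tibble(
    cell_id = rownames(counts), total_reads = unname(total),
    mad = unname(mad_cn), chrom_read_fraction = unname(frac)
  )
}

#' Filter irregular cells
#'
#' Fits a Gaussian to the per-cell MAD distribution and removes cells with
#' `MAD > mu + n_sigma * sigma`; additionally removes cells with more than
#' `chrom_frac_max` of their reads on a single chromosome, and any manually
#' curated exclusions.
#'
#' @param qc Tibble from [cell_qc()].
#' @param n_sigma MAD threshold in standard deviations above the mean
#'   (default 3).
#' @param chrom_frac_max Maximum tolerated single-chromosome read fraction
#'   (default 0.80).
#' @param manual_exclude Character vector of cell ids to drop with reason
#'   `MANUAL`.
#' @return A `scoval_qc` object: the `qc` tibble plus `keep` (logical) and
#'   `reason` (`NA`, `"MAD"`, `"CHROM_FRACTION"`, `"MANUAL"`), with
#'   attributes `mad_mu` and `mad_sigma`.
#' @export
filter_cells <- function(qc, n_sigma = 3, chrom_frac_max = 0.80,
                         manual_exclude = character()) {
  if (nrow(qc) < 10) {
    warning("fewer than 10 cells; the MAD Gaussian fit is unreliable")
  }
  mu <- mean(qc$mad)
  sigma <- stats::sd(qc$mad)
  if (!is.finite(sigma) || sigma == 0) {
    warning("degenerate MAD distribution (sigma = 0); no MAD removals")
    sigma <- 0
    mad_bad <- rep(FALSE, nrow(qc))
  } else {
    mad_bad <- qc$mad > mu + n_sigma * sigma
  }
  out <- qc |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$cell_id %in% manual_exclude ~ "MANUAL",
        mad_bad ~ "MAD",
        .data$chrom_read_fraction > chrom_frac_max ~ "CHROM_FRACTION",
        TRUE ~ NA_character_
      ),
      keep = is.na(.data$reason)
    )
  structure(out, mad_mu = mu, mad_sigma = sigma,
            class = c("scoval_qc", class(out)))
}

#' @export
glance.scoval_qc <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x), n_removed = sum(!x$keep),
    mad_mu = attr(x, "mad_mu"), mad_sigma = attr(x, "mad_sigma"),
    mad_threshold = attr(x, "mad_mu") + 3 * attr(x, "mad_sigma")
  )
}

# ---- circular binary segmentation -----------------------------------------

# Recursive CBS on one numeric vector. Returns sorted change-point positions
# (a change-point at k means a boundary between positions k and k+1,
# 1 <= k <= n-1).
cbs_recurse <- function(x, alpha, nperm, crit = NULL) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(integer())
  sc <- cbs_scan(x)
  accept <- if (is.null(crit)) {
    cbs_perm_pvalue(x, sc$tmax, nperm, alpha) < alpha
  } else {
    sc$tmax >= crit
  }
  if (!accept) return(integer())
  bps <- sort(unique(c(
    if (sc$i > 0) sc$i,
    if (sc$j < n) sc$j
  )))
  if (length(bps) == 0) return(integer())
  bounds <- c(0, bps, n)
  out <- bps
  for (s in seq_len(length(bounds) - 1)) {
    lo <- bounds[s] + 1
    hi <- bounds[s + 1]
    sub <- cbs_recurse(x[lo:hi], alpha, nperm, crit)
    out <- c(out, sub + lo - 1)
  }
  sort(unique(out))
}

# Undo weak splits: merge adjacent segments whose mean difference is at most
# undo_sd times the intra-segment noise SD, weakest first. The noise SD is
# the robust high-pass estimate mad(diff(x)) / sqrt(2): unlike a pooled
# within-segment SD it is not inflated by regionally correlated baseline
# drift, so the rule measures the split against bin-to-bin noise only.
undo_splits <- function(x, bps, undo_sd) {
  if (length(bps) == 0) return(bps)
  sd_est <- if (length(x) >= 3) {
    stats::mad(diff(x)) / sqrt(2)
  } else {
    stats::sd(x)
  }
  repeat {
    if (length(bps) == 0) return(bps)
    bounds <- c(0, bps, length(x))
    k <- length(bounds) - 1
    mns <- vapply(seq_len(k), function(s) {
      mean(x[(bounds[s] + 1):bounds[s + 1]])
    }, numeric(1))
    d <- abs(diff(mns))
    worst <- which.min(d)
    merge_ok <- if (sd_est > 0) d[worst] <= undo_sd * sd_est else
      d[worst] == 0
    if (merge_ok) bps <- bps[-worst] else return(bps)
  }
}

#' Segment one copy-number vector by circular binary segmentation
#'
#' Low-level entry point: recursively places change-points at the circular
#' arc maximising the standardized mean-shift statistic, accepting a split
#' only when its permutation p value is below `alpha`, then undoes any
#' adjacent split whose mean difference is at most `undo_sd` times the
#' pooled intra-segment standard deviation.
#'
#' @param x Numeric vector (one chromosome's values, any scale).
#' @param alpha Split acceptance level (default 0.01).
#' @param undo_sd Undo threshold in pooled intra-segment SDs (default 3).
#' @param nperm Permutations per split test (default 1000).
#' @param crit Optional fixed critical value for the max arc statistic;
#'   when given, a split is accepted iff `tmax >= crit` and no permutation
#'   test is run (deterministic mode, used for oracle comparisons).
#' @return Sorted integer change-point positions: a value `k` marks a
#'   boundary between positions `k` and `k + 1`.
#' @export
cbs_segment <- function(x, alpha = 0.01, undo_sd = 3, nperm = 1000,
                        crit = NULL) {
  if (length(x) < 2) return(integer())
  undo_splits(x, cbs_recurse(x, alpha, nperm, crit), undo_sd)
}

#' Segment copy-number profiles by circular binary segmentation
#'
#' Per cell and chromosome, runs [cbs_segment()] on the copy-number
#' profile. Segmentation operates on the `log2(cn / 2)` ratio scale, where
#' multiplicative amplification noise is homoscedastic and a heterozygous
#' deletion is a unit shift — the scale read-depth segmenters conventionally
#' use; reported segment summaries are in copy-number units. Masked (`NA`)
#' bins are skipped; segments keep genomic coordinates of their first and
#' last unmasked bin.
#'
#' @param cn Copy-number matrix (cells x bins) from [normalize_cells()].
#' @param bins Bin table from [make_variable_bins()].
#' @param alpha Split acceptance level (default 0.01).
#' @param undo_sd Undo threshold in pooled intra-segment SDs on the log2
#'   scale (default 3).
#' @param nperm Permutations per split test (default 1000).
#' @param seed Optional RNG seed for the permutation tests.
#' @param cn_floor Copy-number floor before the log transform (default
#'   0.05), keeping homozygous losses finite.
#' @return Tibble with `cell_id`, `chrom`, `first_bin`, `last_bin` (global
#'   bin indices, inclusive), `start`, `end` (bp), `n_bins`, `median_cn`,
#'   `mean_cn`.
#' @export
segment_cells <- function(cn, bins, alpha = 0.01, undo_sd = 3,
                          nperm = 1000, seed = NULL, cn_floor = 0.05) {
  stopifnot(ncol(cn) == nrow(bins))
  if (!is.null(seed)) set.seed(seed)
  cells <- rownames(cn)
  chroms <- unique(bins$chrom)
  res <- vector("list", length(cells) * length(chroms))
  z <- 0
  for (ci in seq_along(cells)) {
    for (ch in chroms) {
      idx <- which(bins$chrom == ch & is.finite(cn[ci, ]))
      if (length(idx) == 0) next
      x <- cn[ci, idx]
      y <- log2(pmax(x, cn_floor) / 2)
      bps <- cbs_segment(y, alpha, undo_sd, nperm)
      bounds <- c(0, bps, length(x))
      z <- z + 1
      res[[z]] <- tibble::tibble(
        cell_id = cells[ci], chrom = ch,
        first_bin = bins$bin[idx][bounds[-length(bounds)] + 1],
        last_bin = bins$bin[idx][bounds[-1]],
        n_bins = diff(bounds),
        median_cn = vapply(seq_len(length(bounds) - 1), function(s) {
          stats::median(x[(bounds[s] + 1):bounds[s + 1]])
        }, numeric(1)),
        mean_cn = vapply(seq_len(length(bounds) - 1), function(s) {
          mean(x[(bounds[s] + 1):bounds[s + 1]])
        }, numeric(1))
      )
    }
  }
  out <- dplyr::bind_rows(res[seq_len(z)])
  out$start <- bins$start[out$first_bin]
  out$end <- bins$end[out$last_bin]
  dplyr::relocate(out, "start", "end", .after = "chrom")
}

# ---- copy-number cutoff calibration ---------------------------------------

#' Calibrate copy-number calling cutoffs with a Gaussian mixture
#'
#' Fits a Gaussian mixture (EM, components initialised at the integer copy
#' numbers in `components`) to the pooled distribution of segment median
#' copy numbers from all cells. The deletion cutoff is the equal
#' weighted-density crossing between the CN = 1 and CN = 2 components; the
#' duplication cutoff the crossing between CN = 2 and CN = 3. When a flank
#' component carries negligible weight (fewer candidate segments than the
#' mixture can estimate), the corresponding cutoff falls back to the
#' configured default with a warning.
#'
#' @param segment_medians Numeric vector of segment median copy numbers.
#' @param components Integer copy-number states to initialise at
#'   (default `c(1, 2, 3)`; include 0 to model homozygous-deletion mass).
#' @param del_default,dup_default Fallback cutoffs (defaults 1.63 and 2.43).
#' @param min_weight Minimum component weight for a data-driven cutoff
#'   (default 1e-3).
#' @param method `"density"` for the equal weighted-density crossing
#'   (default) or `"tailmass"` for the equal tail-mass point between the two
#'   components.
#' @return A `scoval_calibration`: list with `means`, `sds`, `weights`,
#'   `components`, `del_cutoff`, `dup_cutoff`, `method`, `n`.
#' @export
fit_cutoff_gmm <- function(segment_medians, components = c(1, 2, 3),
                           del_default = 1.63, dup_default = 2.43,
                           min_weight = 1e-3,
                           method = c("density", "tailmass")) {
  method <- match.arg(method)
  x <- segment_medians[is.finite(segment_medians)]
  if (length(x) < 100) {
    warning("fewer than 100 segment medians; calibration may be unstable")
  }
  components <- sort(components)
  fit <- fit_gmm_1d(x, init_means = components)
  ord <- order(fit$means)
  mu <- fit$means[ord]; sg <- fit$sds[ord]; w <- fit$weights[ord]
  names(mu) <- names(sg) <- names(w) <- as.character(components)
  cross <- function(lab1, lab2, default, what) {
    i <- match(lab1, names(mu)); j <- match(lab2, names(mu))
    if (is.na(i) || is.na(j) || w[i] < min_weight || w[j] < min_weight) {
      warning("negligible ", what, " component mass; falling back to ",
              "default cutoff ", default)
      return(default)
    }
    out <- if (method == "density") {
      gmm_crossing(w[i], mu[i], sg[i], w[j], mu[j], sg[j])
    } else {
      gmm_tail_crossing(mu[i], sg[i], mu[j], sg[j])
    }
    if (!is.finite(out)) {
      warning("no ", what, " crossing between component means; falling ",
              "back to default cutoff ", default)
      return(default)
    }
    unname(out)
  }
  del <- cross("1", "2", del_default, "deletion")
  dup <- cross("2", "3", dup_default, "duplication")
  structure(
    list(means = unname(mu), sds = unname(sg), weights = unname(w),
         components = components, del_cutoff = del, dup_cutoff = dup,
         method = method, n = length(x)),
    class = "scoval_calibration"
  )
}

#' @export
print.scoval_calibration <- function(x, ...) {
  cat("<scoval_calibration> fitted on", x$n, "segment medians\n")
  cat("  components (CN):", paste(x$components, collapse = ", "), "\n")
  cat("  means:  ", paste(round(x$means, 3), collapse = ", "), "\n")
  cat("  weights:", paste(signif(x$weights, 3), collapse = ", "), "\n")
  cat("  deletion cutoff:", round(x$del_cutoff, 3),
      " duplication cutoff:", round(x$dup_cutoff, 3), "\n")
  invisible(x)
}

#' @export
tidy.scoval_calibration <- function(x, ...) {
  tibble::tibble(
    component = x$components, mean = x$means, sd = x$sds, weight = x$weights
  )
}

#' @export
glance.scoval_calibration <- function(x, ...) {
  tibble::tibble(
    del_cutoff = x$del_cutoff, dup_cutoff = x$dup_cutoff,
    n = x$n, method = x$method
  )
}

#' Call raw read-depth CNVs from segments
#'
#' Segments with median copy number below the deletion cutoff become
#' deletion candidates (provisionally homozygous when below
#' `hom_threshold`), above the duplication cutoff duplication candidates.
#' Adjacent same-state segments are merged, and only candidates whose
#' genomic span exceeds `min_size` are kept.
#'
#' @param segments Segment tibble from [segment_cells()].
#' @param calibration A `scoval_calibration` (or list with `del_cutoff`,
#'   `dup_cutoff`).
#' @param bins Bin table (for coordinates of merged candidates).
#' @param min_size Minimum genomic span in bp, exclusive (default 1 Mb).
#' @param hom_threshold Copy number below which a deletion is provisionally
#'   homozygous (default 0.5).
#' @return Tibble of raw calls: `cell_id`, `chrom`, `start`, `end`, `type`
#'   (`HET_DEL`/`HOM_DEL`/`DUP`), `median_cn`, `first_bin`, `last_bin`,
#'   `n_bins`, `status = "RAW"`.
#' @export
call_raw_cnvs <- function(segments, calibration, bins, min_size = 1e6,
                          hom_threshold = 0.5) {
  segs <- segments |>
    dplyr::mutate(state = dplyr::case_when(
      .data$median_cn < hom_threshold &
        .data$median_cn < calibration$del_cutoff ~ "HOM_DEL",
      .data$median_cn < calibration$del_cutoff ~ "HET_DEL",
      .data$median_cn > calibration$dup_cutoff ~ "DUP",
      TRUE ~ "NEUTRAL"
    )) |>
    dplyr::arrange(.data$cell_id, .data$first_bin)
  segs <- segs |>
    dplyr::group_by(.data$cell_id, .data$chrom) |>
    dplyr::mutate(run = cumsum(
      c(TRUE, .data$state[-1] != .data$state[-dplyr::n()])
    )) |>
    dplyr::ungroup()
  calls <- segs |>
    dplyr::filter(.data$state != "NEUTRAL") |>
    dplyr::group_by(.data$cell_id, .data$chrom, .data$run, .data$state) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      first_bin = min(.data$first_bin), last_bin = max(.data$last_bin),
      n_bins = sum(.data$n_bins),
      median_cn = stats::median(rep(.data$median_cn, .data$n_bins)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$end - .data$start > min_size) |>
    dplyr::transmute(
      cell_id = .data$cell_id, chrom = .data$chrom, start = .data$start,
      end = .data$end, type = .data$state, median_cn = .data$median_cn,
      first_bin = .data$first_bin, last_bin = .data$last_bin,
      n_bins = .data$n_bins, status = "RAW"
    ) |>
    dplyr::arrange(.data$cell_id, .data$chrom, .data$start)
  calls
}
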