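# one-sided Welch t-test (alternative: x > y) robust to constant data
welch_greater <- function(x, y) {
  if (stats::var(x) + stats::var(y) == 0 || length(x) < 2 ||
        length(y) < 2) {
    d <- mean(x) - mean(y)
    p <- if (d > 0) 0 else if (d < 0) 1 else 0.5
    return(list(statistic = NA_real_, p.value = p))
  }
  stats::t.test(x, y, alternative = "greater")
}

#' Collect CNV breakpoints per bin
#'
#' Every call contributes two breakpoints: the bin containing its start and
#' the bin containing its last base. Bins accumulating two or more
#' breakpoints across all cells are recurrent breakpoint bins (CNVBs).
#' Because bins vary in width, a size-normalized count (breakpoints per bp)
#' is reported alongside the raw count. A boundary falling in masked
#' territory is assigned to the nearest unmasked bin and flagged.
#'
#' @param calls Final call tibble (`cell_id`, `chrom`, `start`, `end`).
#' @param bins Bin table from [make_variable_bins()].
#' @param masked_bins Integer indices of masked bins.
#' @return Tibble with one row per bin that received any breakpoint:
#'   `bin`, `chrom`, `start`, `end`, `breakpoint_count`,
#'   `normalized_count`, `is_cnvb`, `n_reassigned`.
#' @export
collect_breakpoints <- function(calls, bins, masked_bins = integer()) {
  ok <- setdiff(seq_len(nrow(bins)), masked_bins)
  find_bin <- function(chrom, pos) {
    vapply(seq_along(chrom), function(i) {
      cand <- ok[bins$chrom[ok] == chrom[i]]
      inb <- cand[bins$start[cand] <= pos[i] & bins$end[cand] > pos[i]]
      if (length(inb) >= 1) return(c(inb[1], 0))
      # nearest unmasked bin on the chromosome
      d <- pmax(bins$start[cand] - pos[i], pos[i] - bins$end[cand] + 1, 0)
      c(cand[which.min(d)], 1)
    }, numeric(2))
  }
  sb <- find_bin(calls$chrom, calls$start)
  eb <- find_bin(calls$chrom, calls$end - 1)
  bp_bins <- c(sb[1, ], eb[1, ])
  n_re <- sum(sb[2, ], eb[2, ])
  tab <- table(bp_bins)
  idx <- as.integer(names(tab))
  out <- tibble::tibble(
    bin = idx, chrom = bins$chrom[idx], start = bins$start[idx],
    end = bins$end[idx],
    breakpoint_count = as.integer(tab),
    normalized_count = as.integer(tab) / (bins$end[idx] - bins$start[idx]),
    is_cnvb = as.integer(tab) >= 2L
  )
  attr(out, "n_reassigned") <- n_re
  out
}

#' Test whether observed breakpoints cluster beyond the permutation null
#'
#' Compares the size-normalized breakpoint counts of observed CNVB bins
#' against CNVB bins from permuted call sets with a one-sided Welch t-test
#' (alternative: observed > permuted). Also reports the regression slope of
#' permuted breakpoint count on bin size — under random placement the count
#' scales linearly with bin width, while genuinely recurrent breakpoints do
#' not.
#'
#' @param observed_bp Breakpoint tibble from [collect_breakpoints()] on the
#'   real calls.
#' @param perm_calls List of permuted call tibbles (from
#'   [permute_callset()]'s `perm_calls`).
#' @param bins Bin table.
#' @param masked_bins Masked bin indices.
#' @return Tibble with `statistic`, `p_value`, `n_obs_cnvb`,
#'   `n_perm_cnvb`, `perm_slope` (breakpoints per bp of bin width in the
#'   null).
#' @export
breakpoint_clustering_test <- function(observed_bp, perm_calls, bins,
                                       masked_bins = integer()) {
  perm_bp <- dplyr::bind_rows(lapply(perm_calls, collect_breakpoints,
                                     bins = bins,
                                     masked_bins = masked_bins))
  obs <- observed_bp$normalized_count[observed_bp$is_cnvb]
  prm <- perm_bp$normalized_count[perm_bp$is_cnvb]
  if (length(obs) < 2 || length(prm) < 2) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n_obs_cnvb = length(obs),
                          n_perm_cnvb = length(prm),
                          perm_slope = NA_real_))
  }
  tt <- welch_greater(obs, prm)
  # linearity check: mean permuted breakpoints per bin against bin width
  # (all bins, zeros included - random breakpoints land per bp)
  per_bin <- rowsum(perm_bp$breakpoint_count, perm_bp$bin)
  mean_count <- stats::setNames(rep(0, nrow(bins)), bins$bin)
  mean_count[rownames(per_bin)] <- per_bin[, 1] / length(perm_calls)
  width <- bins$end - bins$start
  slope <- if (stats::var(width) > 0) {
    unname(stats::coef(stats::lm(mean_count ~ width))[2])
  } else {
    NA_real_ # constant-width bins carry no size information
  }
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 n_obs_cnvb = length(obs), n_perm_cnvb = length(prm),
                 perm_slope = slope)
}

#' Long-gene enrichment at recurrent breakpoint bins
#'
#' Counts genes longer than `threshold` overlapping each CNVB bin (extended
#' by `extend` bp on both sides), normalized by bin size, and contrasts
#' observed CNVBs against CNVBs from permuted call sets with a one-sided
#' Welch t-test. `fold = (mean_obs - mean_perm) / mean_perm`.
#'
#' @param observed_bp Breakpoint tibble (observed).
#' @param perm_calls List of permuted call tibbles.
#' @param bins Bin table.
#' @param genes Gene tibble (`chrom`, `start`, `end`).
#' @param threshold Long-gene length in bp (default 100 kb).
#' @param extend Bin extension in bp (default 250 kb).
#' @param masked_bins Masked bin indices.
#' @return Tibble with `fold`, `statistic`, `p_value`, `mean_obs`,
#'   `mean_perm` (`NA`s when no gene passes the threshold).
#' @export
long_gene_enrichment <- function(observed_bp, perm_calls, bins, genes,
                                 threshold = 1e5, extend = 2.5e5,
                                 masked_bins = integer()) {
  lg <- genes[genes$end - genes$start > threshold, ]
  if (nrow(lg) == 0) {
    return(tibble::tibble(fold = NA_real_, statistic = NA_real_,
                          p_value = NA_real_, mean_obs = NA_real_,
                          mean_perm = NA_real_))
  }
  norm_counts <- function(bp) {
    b <- bp[bp$is_cnvb, ]
    if (nrow(b) == 0) return(numeric(0))
    ext <- dplyr::mutate(b, start = pmax(.data$start - extend, 0),
                         end = .data$end + extend)
    count_overlaps(ext, lg) / (b$end - b$start)
  }
  obs <- norm_counts(observed_bp)
  prm <- unlist(lapply(perm_calls, function(pc) {
    norm_counts(collect_breakpoints(pc, bins, masked_bins))
  }))
  if (length(obs) < 2 || length(prm) < 2) {
    return(tibble::tibble(fold = NA_real_, statistic = NA_real_,
                          p_value = NA_real_, mean_obs = mean(obs),
                          mean_perm = mean(prm)))
  }
  tt <- welch_greater(obs, prm)
  tibble::tibble(
    fold = (mean(obs) - mean(prm)) / mean(prm),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    mean_obs = mean(obs), mean_perm = mean(prm)
  )
}

#' Expression of the longest gene at recurrent breakpoint bins
#'
#' For each observed CNVB bin and each permuted CNVB bin (both extended by
#' `extend`), takes the TPM of the longest overlapping gene, and compares
#' the two distributions with a one-tailed Welch t-test (alternative:
#' observed > permuted). Regions without an expressed gene are dropped.
#'
#' @param observed_bp Breakpoint tibble (observed).
#' @param perm_calls List of permuted call tibbles.
#' @param bins Bin table.
#' @param genes Gene tibble (`chrom`, `start`, `end`, `gene`).
#' @param tpm Tibble (`gene`, `tpm`).
#' @param extend Bin extension in bp (default 250 kb).
#' @param masked_bins Masked bin indices.
#' @return Tibble with `statistic`, `p_value`, `mean_obs`, `mean_perm`.
#' @export
tpm_comparison <- function(observed_bp, perm_calls, bins, genes, tpm,
                           extend = 2.5e5, masked_bins = integer()) {
  g <- dplyr::inner_join(genes, tpm, by = "gene")
  longest_tpm <- function(bp) {
    b <- bp[bp$is_cnvb, ]
    vapply(seq_len(nrow(b)), function(i) {
      hit <- g[g$chrom == b$chrom[i] & g$start < b$end[i] + extend &
                 g$end > b$start[i] - extend, ]
      if (nrow(hit) == 0) return(NA_real_)
      hit$tpm[which.max(hit$end - hit$start)]
    }, numeric(1))
  }
  obs <- longest_tpm(observed_bp)
  prm <- unlist(lapply(perm_calls, function(pc) {
    longest_tpm(collect_breakpoints(pc, bins, masked_bins))
  }))
  obs <- obs[is.finite(obs)]; prm <- prm[is.finite(prm)]
  if (length(obs) < 2 || length(prm) < 2) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          mean_obs = mean(obs), mean_perm = mean(prm)))
  }
  tt <- welch_greater(obs, prm)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 mean_obs = mean(obs), mean_perm = mean(prm))
}

#' Find recurrent CNVs (CNVRs)
#'
#' CNVs from different cells sharing both their start and end breakpoint
#' bins are grouped into recurrent CNV loci.
#'
#' @param calls Final call tibble with `first_bin` / `last_bin` columns.
#' @return Tibble with `cnvr_id`, `chrom`, `start`, `end`, `first_bin`,
#'   `last_bin`, `n_cells`, `member_cells` (list column).
#' @export
find_cnvrs <- function(calls) {
  calls |>
    dplyr::group_by(.data$chrom, .data$first_bin, .data$last_bin) |>
    dplyr::filter(dplyr::n_distinct(.data$cell_id) >= 2) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_cells = dplyr::n_distinct(.data$cell_id),
      member_cells = list(sort(unique(.data$cell_id))), .groups = "drop"
    ) |>
    dplyr::mutate(cnvr_id = paste0("cnvr", dplyr::row_number()),
                  .before = 1)
}

#' Haplotype-based clonality of a recurrent CNV
#'
#' For each bin inside the CNVR, takes the per-cell signed pseudocount log2
#' allele ratio (median over the cell's windows in that bin), computes
#' `delta = max - min` over member cells, and takes the median delta over
#' bins. Deletions on the same haplotype give concordant signed ratios and
#' a small delta (`SHARED_HAPLOTYPE`); deletions on opposite haplotypes
#' give opposite signs and a delta above `threshold`
#' (`OPPOSITE_HAPLOTYPE`). The classification is invariant to global
#' haplotype relabeling.
#'
#' @param cnvrs CNVR tibble from [find_cnvrs()].
#' @param window_stats Window statistics from [count_informative_reads()].
#' @param snp_windows Result of [build_snp_windows()].
#' @param bins Bin table.
#' @param threshold Delta separating shared from opposite haplotypes
#'   (default 5, the empirical separation of the two delta modes).
#' @param min_members Minimum informative member cells (default 2).
#' @return `cnvrs` with `delta_median_log2`, `n_informative_members`,
#'   `klass` (`SHARED_HAPLOTYPE` / `OPPOSITE_HAPLOTYPE` / `NA` when fewer
#'   than `min_members` members are informative).
#' @export
cnvr_clonality <- function(cnvrs, window_stats, snp_windows, bins,
                           threshold = 5, min_members = 2) {
  windows <- snp_windows$windows
  smat <- stat_matrix(window_stats, "signed_log2_pc")
  delta <- nim <- rep(NA_real_, nrow(cnvrs))
  for (i in seq_len(nrow(cnvrs))) {
    bidx <- cnvrs$first_bin[i]:cnvrs$last_bin[i]
    members <- cnvrs$member_cells[[i]]
    # per bin x member: median signed ratio of the windows in the bin
    deltas <- c()
    informative <- rep(FALSE, length(members))
    for (b in bidx) {
      wid <- windows$window_id[windows$chrom == bins$chrom[b] &
                                 windows$start >= bins$start[b] &
                                 windows$end <= bins$end[b]]
      if (length(wid) == 0) next
      vals <- vapply(members, function(m) {
        if (!m %in% rownames(smat)) return(NA_real_)
        v <- smat[m, wid]
        stats::median(v, na.rm = TRUE)
      }, numeric(1))
      got <- is.finite(vals)
      informative <- informative | got
      if (sum(got) >= min_members) {
        deltas <- c(deltas, max(vals[got]) - min(vals[got]))
      }
    }
    nim[i] <- sum(informative)
    if (length(deltas) > 0 && nim[i] >= min_members) {
      delta[i] <- stats::median(deltas)
    }
  }
  dplyr::mutate(
    cnvrs,
    delta_median_log2 = delta,
    n_informative_members = nim,
    klass = dplyr::case_when(
      is.na(delta) ~ NA_character_,
      delta > threshold ~ "OPPOSITE_HAPLOTYPE",
      TRUE ~ "SHARED_HAPLOTYPE"
    )
  )
}

#' Flag technical-replicate cell pairs
#'
#' Two barcodes capturing the same nucleus show near-identical genome-wide
#' copy-number profiles. Cell pairs with per-bin CN correlation above
#' `cor_threshold` and identical final call sets are flagged so recurrence
#' statistics can count them once.
#'
#' @param cn Copy-number matrix (cells x bins).
#' @param calls Final call tibble.
#' @param cor_threshold Pearson correlation cutoff (default 0.99).
#' @return Tibble of flagged pairs: `cell_a`, `cell_b`, `correlation`,
#'   `identical_calls`.
#' @export
detect_technical_replicates <- function(cn, calls, cor_threshold = 0.99) {
  cc <- stats::cor(t(cn), use = "pairwise.complete.obs")
  idx <- which(upper.tri(cc) & cc > cor_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(cell_a = character(), cell_b = character(),
                          correlation = numeric(),
                          identical_calls = logical()))
  }
  key <- function(cell) {
    k <- calls[calls$cell_id == cell, c("chrom", "start", "end")]
    paste(k$chrom, k$start, k$end, collapse = ";")
  }
  tibble::tibble(
    cell_a = rownames(cc)[idx[, 1]],
    cell_b = rownames(cc)[idx[, 2]],
    correlation = cc[idx],
    identical_calls = vapply(seq_len(nrow(idx)), function(i) {
      key(rownames(cc)[idx[i, 1]]) == key(rownames(cc)[idx[i, 2]])
    }, logical(1))
  )
}
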