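#' Split phase blocks into SNP windows
#'
#' Each phase block (run of consistently phased heterozygous SNPs) is split
#' into `ceiling(n / max_snps)` windows of near-equal SNP count; blocks (or
#' leftover windows) with fewer than `min_snps` SNPs yield no window. The
#' window interval spans the first to last SNP position it contains.
#'
#' @param snps Phased SNP tibble from [read_phased_vcf()] (columns `chrom`,
#'   `pos`, `block_id`, `hap1_allele`, `hap2_allele`).
#' @param min_snps,max_snps Window size bounds (defaults 20 and 100).
#' @return List with `windows` (tibble: `window_id`, `block_id`, `chrom`,
#'   `start`, `end`, `n_snps`) and `snps` (input augmented with
#'   `window_id`, `NA` for SNPs in dropped blocks).
#' @export
build_snp_windows <- function(snps, min_snps = 20, max_snps = 100) {
  stopifnot(nrow(snps) > 0, min_snps >= 1, max_snps >= min_snps)
  snps <- dplyr::arrange(snps, .data$chrom, .data$pos)
  aug <- snps |>
    dplyr::group_by(.data$block_id) |>
    dplyr::mutate(window_id = {
      n <- dplyr::n()
      if (n < min_snps) {
        rep(NA_character_, n)
      } else {
        k <- ceiling(n / max_snps)
        base <- n %/% k
        extra <- n %% k
        sizes <- rep(base, k) + rep(c(1, 0), c(extra, k - extra))
        w <- rep(seq_len(k), sizes)
        ok <- sizes[w] >= min_snps
        ifelse(ok, paste0(.data$block_id[1], ":w", w), NA_character_)
      }
    }) |>
    dplyr::ungroup()
  assigned <- dplyr::filter(aug, !is.na(.data$window_id))
  if (nrow(assigned) == 0) {
    windows <- tibble::tibble(
      window_id = character(), block_id = character(),
      chrom = character(), start = double(), end = double(),
      n_snps = integer()
    )
  } else {
    windows <- assigned |>
      dplyr::group_by(.data$window_id, .data$block_id, .data$chrom) |>
      dplyr::summarise(
        start = min(.data$pos), end = max(.data$pos) + 1,
        n_snps = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::arrange(.data$chrom, .data$start)
  }
  n_dropped <- dplyr::n_distinct(snps$block_id) -
    dplyr::n_distinct(windows$block_id)
  if (n_dropped > 0) {
    message(n_dropped, " phase block(s) below ", min_snps,
            " SNPs yielded no window")
  }
  list(windows = windows, snps = aug)
}

#' Count haplotype-informative reads per SNP window
#'
#' A read overlapping a phased heterozygous SNP is informative: its allele
#' assigns it to one haplotype. Per cell and window this sums the depths of
#' the alleles phased to haplotype 1 and haplotype 2, and computes the
#' log2 allele-ratio statistics:
#' * `abs_log2` / `signed_log2` — the strict form, defined only when each
#'   haplotype has more than `min_reads` reads (used for classifier
#'   backgrounds and duplication assessment);
#' * `abs_log2_pc` / `signed_log2_pc` — a pseudocount form
#'   `log2((h1 + 0.5)/(h2 + 0.5))`, always defined, so a fully lost
#'   haplotype (0 reads) yields a large finite value (used for LOH medians
#'   in candidate regions).
#' Reads at SNPs outside any window are ignored and tallied in the
#' `n_unwindowed_reads` attribute.
#'
#' @param depths Allele-depth tibble (`cell_id`, `chrom`, `pos`,
#'   `ref_depth`, `alt_depth`).
#' @param snp_windows Result of [build_snp_windows()].
#' @param cells Optional character vector of all cell ids; the result is
#'   completed to the full cell-by-window grid with zero counts (a window
#'   with no reads in a cell is evidence, not missing data).
#' @param min_reads Strict-form threshold: each haplotype must exceed this
#'   (default 3).
#' @return Tibble with `cell_id`, `window_id`, `hap1_reads`, `hap2_reads`,
#'   `informative`, `abs_log2`, `signed_log2`, `abs_log2_pc`,
#'   `signed_log2_pc`.
#' @export
count_informative_reads <- function(depths, snp_windows, cells = NULL,
                                    min_reads = 3) {
  snps <- snp_windows$snps
  j <- dplyr::inner_join(
    depths, snps[, c("chrom", "pos", "window_id", "hap1_allele")],
    by = c("chrom", "pos")
  )
  unwindowed <- sum(j$ref_depth[is.na(j$window_id)],
                    j$alt_depth[is.na(j$window_id)])
  j <- dplyr::filter(j, !is.na(.data$window_id))
  j$h1 <- ifelse(j$hap1_allele == "ref", j$ref_depth, j$alt_depth)
  j$h2 <- ifelse(j$hap1_allele == "ref", j$alt_depth, j$ref_depth)
  counts <- j |>
    dplyr::group_by(.data$cell_id, .data$window_id) |>
    dplyr::summarise(hap1_reads = sum(.data$h1),
                     hap2_reads = sum(.data$h2), .groups = "drop")
  if (is.null(cells)) cells <- unique(depths$cell_id)
  grid <- tidyr::expand_grid(
    cell_id = cells, window_id = snp_windows$windows$window_id
  )
  counts <- dplyr::left_join(grid, counts,
                             by = c("cell_id", "window_id")) |>
    dplyr::mutate(
      hap1_reads = dplyr::coalesce(.data$hap1_reads, 0L),
      hap2_reads = dplyr::coalesce(.data$hap2_reads, 0L)
    )
  out <- window_log2_ratio(counts, min_reads = min_reads)
  attr(out, "n_unwindowed_reads") <- unwindowed
  out
}

#' Log2 allele-ratio statistics for haplotype read counts
#'
#' @param counts Tibble with `hap1_reads` and `hap2_reads`.
#' @param min_reads Strict-form threshold (default 3: each haplotype must
#'   have more than 3 reads for the strict statistic).
#' @return `counts` with added `informative`, `abs_log2`, `signed_log2`,
#'   `abs_log2_pc`, `signed_log2_pc`.
#' @export
window_log2_ratio <- function(counts, min_reads = 3) {
  h1 <- counts$hap1_reads
  h2 <- counts$hap2_reads
  strict_ok <- h1 > min_reads & h2 > min_reads
  signed <- ifelse(strict_ok, log2(h1 / h2), NA_real_)
  pc <- log2((h1 + 0.5) / (h2 + 0.5))
  dplyr::mutate(
    counts,
    informative = h1 + h2 > 0,
    abs_log2 = abs(signed),
    signed_log2 = signed,
    abs_log2_pc = abs(pc),
    signed_log2_pc = pc
  )
}

#' Screen calls for germline origin by pooled minor allele frequency
#'
#' A somatic deletion is carried by few cells, so the population-pooled
#' minor allele frequency (MAF) at heterozygous SNPs inside it stays near
#' 0.5; a germline deletion removes one haplotype from every cell and drives
#' the pooled MAF towards 0. Per call this pools allele depths across all
#' cells for each SNP inside the call, computes
#' `MAF = min(ref, alt) / (ref + alt)` and takes the median over SNPs.
#'
#' @param calls Call tibble (`cell_id`, `chrom`, `start`, `end`, ...).
#' @param depths Allele-depth tibble for all cells.
#' @param snps Phased SNP tibble (defines which sites are germline het).
#' @param maf_floor Median-MAF floor below which a call is flagged
#'   `germline_suspect` (default 0.40).
#' @return `calls` with added `median_maf` (`NA` when no covered SNP) and
#'   `germline_suspect`.
#' @export
germline_maf_screen <- function(calls, depths, snps, maf_floor = 0.40) {
  pooled <- depths |>
    dplyr::semi_join(snps, by = c("chrom", "pos")) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(ref = sum(.data$ref_depth), alt = sum(.data$alt_depth),
                     .groups = "drop") |>
    dplyr::filter(.data$ref + .data$alt > 0) |>
    dplyr::mutate(maf = pmin(.data$ref, .data$alt) /
                    (.data$ref + .data$alt))
  med <- vapply(seq_len(nrow(calls)), function(i) {
    m <- pooled$maf[pooled$chrom == calls$chrom[i] &
                      pooled$pos >= calls$start[i] &
                      pooled$pos < calls$end[i]]
    if (length(m) == 0) NA_real_ else stats::median(m)
  }, numeric(1))
  dplyr::mutate(calls, median_maf = med,
                germline_suspect = is.na(med) | med < maf_floor)
}

#' Extend phase blocks to chromosome scale using large deletions
#'
#' Within one cell, every phase block covered by the same deletion retains
#' the same physical homolog; the sign of the signed pseudocount log2 ratio
#' says which labelled haplotype that is in each block. Blocks are therefore
#' re-orientable (KEEP/FLIP of the hap1/hap2 labels) so that the retained
#' haplotype is consistent within each cell, and orientation propagates
#' transitively across cells whose deletions overlap. Majority voting with
#' an agreement threshold guards against noisy windows; blocks that receive
#' conflicting votes (majority ratio below `min_agreement`) or no votes are
#' `UNRESOLVED`.
#'
#' @param window_stats Per-cell window statistics from
#'   [count_informative_reads()].
#' @param snp_windows Result of [build_snp_windows()] (maps windows to
#'   blocks).
#' @param deletions Deletion calls used for extension (`cell_id`, `chrom`,
#'   `start`, `end`), typically large validated heterozygous deletions.
#' @param min_agreement Majority-vote ratio below which a block is
#'   `UNRESOLVED` (default 0.8).
#' @param min_windows Minimum informative windows per (cell, block)
#'   observation (default 1).
#' @return Tibble with `block_id`, `orientation`
#'   (`KEEP`/`FLIP`/`UNRESOLVED`), `n_votes`, `agreement`. Attribute
#'   `cell_homolog` gives the deleted-homolog sign assigned to each cell.
#' @export
extend_phase_blocks <- function(window_stats, snp_windows, deletions,
                                min_agreement = 0.8, min_windows = 1) {
  windows <- snp_windows$windows
  blocks <- unique(windows$block_id)
  out <- tibble::tibble(block_id = blocks, orientation = "UNRESOLVED",
                        n_votes = 0L, agreement = NA_real_)
  if (nrow(deletions) == 0) return(out)
  # per (cell, block) retained-haplotype sign inside that cell's deletions
  obs_list <- lapply(seq_len(nrow(deletions)), function(i) {
    w <- windows[windows$chrom == deletions$chrom[i] &
                   windows$start >= deletions$start[i] &
                   windows$end <= deletions$end[i], ]
    if (nrow(w) == 0) return(NULL)
    st <- window_stats[window_stats$cell_id == deletions$cell_id[i] &
                         window_stats$window_id %in% w$window_id &
                         window_stats$informative, ]
    if (nrow(st) == 0) return(NULL)
    st <- dplyr::left_join(st, w[, c("window_id", "block_id")],
                           by = "window_id")
    st |>
      dplyr::group_by(.data$block_id) |>
      dplyr::summarise(s = stats::median(.data$signed_log2_pc),
                       nw = dplyr::n(), .groups = "drop") |>
      dplyr::filter(.data$nw >= min_windows, .data$s != 0) |>
      dplyr::transmute(cell_id = deletions$cell_id[i],
                       block_id = .data$block_id, s = sign(.data$s))
  })
  obs <- dplyr::bind_rows(obs_list)
  if (nrow(obs) == 0) return(out)
  obs <- obs |>
    dplyr::group_by(.data$cell_id, .data$block_id) |>
    dplyr::summarise(s = sign(sum(.data$s)), .groups = "drop") |>
    dplyr::filter(.data$s != 0)
  # propagate orientations over the bipartite cell/block graph
  o_block <- stats::setNames(rep(NA_real_, length(blocks)), blocks)
  h_cell <- stats::setNames(rep(NA_real_, length(unique(obs$cell_id))),
                            unique(obs$cell_id))
  repeat {
    seedable <- setdiff(unique(obs$block_id), names(o_block)[!is.na(o_block)])
    if (length(seedable) == 0) break
    o_block[seedable[1]] <- 1
    repeat {
      changed <- FALSE
      for (cid in names(h_cell)[is.na(h_cell)]) {
        e <- obs[obs$cell_id == cid & !is.na(o_block[obs$block_id]), ]
        if (nrow(e) > 0) {
          h_cell[cid] <- sign(sum(e$s * o_block[e$block_id]))
          if (h_cell[cid] == 0) h_cell[cid] <- e$s[1] * o_block[e$block_id[1]]
          changed <- TRUE
        }
      }
      for (bid in names(o_block)[is.na(o_block)]) {
        e <- obs[obs$block_id == bid & !is.na(h_cell[obs$cell_id]), ]
        if (nrow(e) > 0) {
          v <- sign(sum(e$s * h_cell[e$cell_id]))
          o_block[bid] <- if (v == 0) e$s[1] * h_cell[e$cell_id[1]] else v
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  # vote agreement per block under the fitted assignment
  stat <- obs |>
    dplyr::filter(!is.na(o_block[.data$block_id]),
                  !is.na(h_cell[.data$cell_id])) |>
    dplyr::mutate(agree = .data$s * h_cell[.data$cell_id] ==
                    o_block[.data$block_id]) |>
    dplyr::group_by(.data$block_id) |>
    dplyr::summarise(n_votes = dplyr::n(),
                     agreement = max(mean(.data$agree),
                                     1 - mean(.data$agree)),
                     .groups = "drop")
  out <- out |>
    dplyr::select(-"n_votes", -"agreement") |>
    dplyr::left_join(stat, by = "block_id") |>
    dplyr::mutate(
      n_votes = dplyr::coalesce(.data$n_votes, 0L),
      orientation = dplyr::case_when(
        .data$n_votes == 0 ~ "UNRESOLVED",
        .data$agreement < min_agreement ~ "UNRESOLVED",
        o_block[.data$block_id] > 0 ~ "KEEP",
        TRUE ~ "FLIP"
      )
    )
  attr(out, "cell_homolog") <- h_cell
  out
}
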