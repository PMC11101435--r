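#' Specify planted CNV events for the simulator
#'
#' @param n Number of events.
#' @param type `"HET_DEL"`, `"HOM_DEL"`, `"DUP"` or `"MONOSOMY"`.
#' @param min_len,max_len Event length range in bp (ignored for
#'   `MONOSOMY`). Planted events meant to be detectable should exceed
#'   1 Mb.
#' @param haplotype `"1"`, `"2"` or `"random"`.
#' @param chrom,start Optional fixed locus (recycled) for planting
#'   recurrence; `NA` places uniformly at random.
#' @param cell Optional cell index (1-based) to receive the event; `NA`
#'   picks cells at random without replacement across all events when
#'   possible.
#' @return Event-spec tibble; concatenate specs with [dplyr::bind_rows()].
#' @export
sim_events <- function(n = 50, type = "HET_DEL", min_len = 2e6,
                       max_len = 2e7, haplotype = "random", chrom = NA,
                       start = NA, cell = NA) {
  tibble::tibble(
    type = type, min_len = min_len, max_len = max_len,
    haplotype = as.character(haplotype), chrom = as.character(chrom),
    start = as.numeric(start), cell = as.numeric(cell),
    .rows = n
  )
}

#' Simulator configuration
#'
#' Defaults emulate droplet-WGA single-cell sequencing of neuronal nuclei
#' at ~0.1x coverage: roughly 450 reads per 500 kb-mappable bin per cell
#' with lognormal per-bin amplification noise, phased heterozygous SNPs at
#' ~1 per kb organised in lognormally sized phase blocks, and sparse
#' haplotype-informative reads (about 5 per haplotype in a 100-SNP
#' window).
#'
#' @param n_cells Number of cells (default 200).
#' @param chrom_lengths Named vector of chromosome lengths (default two
#'   synthetic chromosomes, 120 Mb and 80 Mb).
#' @param bin_target Mappable bp per bin (default 500 kb).
#' @param reads_per_bin Mean reads per bin per cell (default 450).
#' @param cell_depth_sdlog Lognormal SD of per-cell depth factors (default
#'   0.35, matching the wide read-count spread of pooled single-nucleus
#'   libraries).
#' @param amp_sigma Lognormal sigma of per-bin amplification factors
#'   (default 0.12; together with the regional bias this yields per-cell
#'   copy-number MADs around 0.15-0.3, the QC-relevant range).
#' @param region_sigma Lognormal sigma of regionally correlated
#'   amplification bias (default 0.08): WGA over- or under-amplifies
#'   multi-megabase stretches coherently, which is what makes read-depth
#'   false positives possible and keeps segment-median distributions
#'   realistically wide.
#' @param region_len_bins Mean length (bins, geometric) of the correlated
#'   bias blocks (default 20).
#' @param snp_per_kb Phased het-SNP density (default 1).
#' @param block_meanlog,block_sdlog Phase-block length distribution
#'   (defaults log(234 kb) and 1.8: median a few hundred kb, mean above
#'   1 Mb, occasional multi-Mb blocks).
#' @param hap_cov Expected informative reads per SNP per haplotype copy
#'   (default 0.05).
#' @param bulk_reads_per_bin Bulk (germline diploid) coverage per bin
#'   (default 5000).
#' @param events Event-spec tibble from [sim_events()] (default 50
#'   heterozygous deletions of 2-20 Mb on random haplotypes in random
#'   cells).
#' @param snap_to_bins Snap event boundaries to bin boundaries (default
#'   `TRUE`; read-depth detection is bin-resolution anyway and snapping
#'   makes planted recurrence exact).
#' @param germline_deletion Optional `list(chrom=, start=, end=,
#'   haplotype=)` deleted in every cell.
#' @param technical_replicate_pairs Number of duplicated-barcode pairs to
#'   append (default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 200,
                       chrom_lengths = c(sim1 = 120e6, sim2 = 80e6),
                       bin_target = 5e5, reads_per_bin = 450,
                       cell_depth_sdlog = 0.35, amp_sigma = 0.12,
                       region_sigma = 0.08, region_len_bins = 20,
                       snp_per_kb = 1,
                       block_meanlog = log(234e3), block_sdlog = 1.8,
                       hap_cov = 0.05, bulk_reads_per_bin = 5000,
                       events = sim_events(),
                       snap_to_bins = TRUE,
                       germline_deletion = NULL,
                       technical_replicate_pairs = 0) {
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a full single-cell CNV dataset with known truth
#'
#' Produces every input the pipeline consumes — cells-by-bins counts, a
#' phased SNP set with phase blocks, per-cell per-SNP allele depths, bulk
#' bin counts — plus the planted-event truth set. Bin counts are Poisson
#' draws around copy-number x lognormal amplification factor x cell depth;
#' the deleted haplotype contributes no reads in its interval; informative
#' reads are sampled per haplotype proportional to local haplotype copy
#' number. Deterministic under a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param seed RNG seed (default 1).
#' @return A `scoval_sim` list: `layout`, `bins`, `counts`, `snps`,
#'   `depths`, `bulk`, `truth`, `replicate_pairs`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  layout <- genome_layout(tibble::tibble(
    chrom = names(cfg$chrom_lengths), length = unname(cfg$chrom_lengths)
  ))
  bins <- make_variable_bins(layout, cfg$bin_target)
  n_bins <- nrow(bins)
  n_cells <- cfg$n_cells
  cells <- sprintf("cell%03d", seq_len(n_cells))

  truth <- place_truth_events(cfg, layout, bins, cells)
  if (!is.null(cfg$germline_deletion)) {
    g <- cfg$germline_deletion
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      cell_id = cells, chrom = g$chrom, start = g$start, end = g$end,
      type = "GERMLINE_DEL", haplotype = as.character(g$haplotype)
    ))
  }

  # per-cell per-bin haplotype copy numbers
  hap_cn <- function(cell, hap) {
    cn <- rep(1, n_bins)
    ev <- truth[truth$cell_id == cell &
                  (truth$haplotype == hap | truth$type == "HOM_DEL"), ]
    for (i in seq_len(nrow(ev))) {
      frac <- pmin(bins$end, ev$end[i]) - pmax(bins$start, ev$start[i])
      frac <- pmax(frac, 0) / (bins$end - bins$start)
      frac[bins$chrom != ev$chrom[i]] <- 0
      if (ev$type[i] == "DUP") cn <- cn + frac else cn <- cn - frac
    }
    pmax(cn, 0)
  }
  h1 <- t(vapply(cells, hap_cn, numeric(n_bins), hap = "1"))
  h2 <- t(vapply(cells, hap_cn, numeric(n_bins), hap = "2"))

  depth <- stats::rlnorm(n_cells, -cfg$cell_depth_sdlog^2 / 2,
                         cfg$cell_depth_sdlog)
  amp <- matrix(stats::rlnorm(n_cells * n_bins, -cfg$amp_sigma^2 / 2,
                              cfg$amp_sigma), n_cells, n_bins)
  # regionally correlated WGA bias: piecewise-constant multiplicative
  # blocks of geometric length, independent per cell
  if (cfg$region_sigma > 0) {
    for (i in seq_len(n_cells)) {
      pos <- 1
      while (pos <= n_bins) {
        len <- 1 + stats::rgeom(1, 1 / cfg$region_len_bins)
        hi <- min(pos + len - 1, n_bins)
        amp[i, pos:hi] <- amp[i, pos:hi] *
          stats::rlnorm(1, -cfg$region_sigma^2 / 2, cfg$region_sigma)
        pos <- hi + 1
      }
    }
  }

  # technical replicates share the expected profile (same amplification)
  rep_pairs <- tibble::tibble(cell_a = character(), cell_b = character())
  if (cfg$technical_replicate_pairs > 0) {
    src <- seq_len(cfg$technical_replicate_pairs)
    for (k in src) {
      newc <- sprintf("cell%03dr", k)
      cells <- c(cells, newc)
      h1 <- rbind(h1, h1[k, ]); h2 <- rbind(h2, h2[k, ])
      amp <- rbind(amp, amp[k, ])
      depth <- c(depth, depth[k])
      tr <- truth[truth$cell_id == sprintf("cell%03d", k), ]
      if (nrow(tr) > 0) {
        tr$cell_id <- newc
        truth <- dplyr::bind_rows(truth, tr)
      }
      rep_pairs <- dplyr::bind_rows(rep_pairs, tibble::tibble(
        cell_a = sprintf("cell%03d", k), cell_b = newc
      ))
    }
    n_cells <- length(cells)
  }
  rownames(h1) <- rownames(h2) <- rownames(amp) <- cells

  lambda <- cfg$reads_per_bin * depth * amp * (h1 + h2) / 2
  counts <- matrix(stats::rpois(length(lambda), lambda), n_cells, n_bins,
                   dimnames = list(cells, paste0("bin", bins$bin)))

  bulk <- stats::rpois(n_bins, cfg$bulk_reads_per_bin)

  snps <- simulate_phased_snps(cfg, layout)
  depths <- simulate_allele_depths(cfg, snps, truth, cells, bins)

  structure(
    list(layout = layout, bins = bins, counts = counts, snps = snps,
         depths = depths, bulk = bulk, truth = truth,
         replicate_pairs = rep_pairs, cfg = cfg),
    class = "scoval_sim"
  )
}

# place events per the spec; events never overlap within a cell
place_truth_events <- function(cfg, layout, bins, cells) {
  ev <- cfg$events
  if (is.null(ev) || nrow(ev) == 0) {
    return(tibble::tibble(cell_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          type = character(), haplotype = character()))
  }
  chroms <- layout$chromosomes
  free_cells <- sample(seq_along(cells))
  out <- vector("list", nrow(ev))
  placed <- list() # per cell list of intervals
  for (i in seq_len(nrow(ev))) {
    ci <- if (!is.na(ev$cell[i])) ev$cell[i] else {
      if (length(free_cells) > 0) {
        x <- free_cells[1]; free_cells <- free_cells[-1]; x
      } else sample(seq_along(cells), 1)
    }
    cell <- cells[ci]
    hap <- if (ev$haplotype[i] == "random") sample(c("1", "2"), 1) else
      ev$haplotype[i]
    if (ev$type[i] == "MONOSOMY") {
      ch <- if (!is.na(ev$chrom[i])) ev$chrom[i] else
        sample(chroms$chrom, 1)
      st <- 0; en <- chroms$length[chroms$chrom == ch]
    } else {
      for (t in 1:1000) {
        len <- stats::runif(1, ev$min_len[i], ev$max_len[i])
        ch <- if (!is.na(ev$chrom[i])) ev$chrom[i] else {
          ok <- chroms[chroms$length >= len, ]
          ok$chrom[sample.int(nrow(ok), 1, prob = ok$length)]
        }
        st <- if (!is.na(ev$start[i])) ev$start[i] else
          floor(stats::runif(1, 0, chroms$length[chroms$chrom == ch] - len))
        en <- min(st + len, chroms$length[chroms$chrom == ch])
        if (isTRUE(cfg$snap_to_bins)) {
          b <- bins[bins$chrom == ch, ]
          st <- max(b$start[b$start <= st])
          en <- min(b$end[b$end >= en])
        }
        prev <- placed[[cell]]
        clash <- !is.null(prev) &&
          any(prev$chrom == ch & prev$start < en & prev$end > st)
        if (!clash) break
        if (t == 1000) stop("could not place event without overlap")
      }
    }
    placed[[cell]] <- dplyr::bind_rows(
      placed[[cell]], tibble::tibble(chrom = ch, start = st, end = en)
    )
    out[[i]] <- tibble::tibble(cell_id = cell, chrom = ch, start = st,
                               end = en, type = ev$type[i], haplotype = hap)
  }
  dplyr::bind_rows(out)
}

# phased het-SNPs with lognormal phase blocks; hap1 allele random
simulate_phased_snps <- function(cfg, layout) {
  out <- vector("list", nrow(layout$chromosomes))
  for (ci in seq_len(nrow(layout$chromosomes))) {
    ch <- layout$chromosomes$chrom[ci]
    len <- layout$chromosomes$length[ci]
    n_snp <- stats::rpois(1, len / 1000 * cfg$snp_per_kb)
    pos <- sort(sample.int(len, n_snp))
    # phase blocks tile the chromosome with lognormal lengths
    bl <- c(0)
    while (utils::tail(bl, 1) < len) {
      bl <- c(bl, utils::tail(bl, 1) +
                stats::rlnorm(1, cfg$block_meanlog, cfg$block_sdlog))
    }
    block <- findInterval(pos, bl, left.open = FALSE)
    hap1 <- sample(c("ref", "alt"), n_snp, replace = TRUE)
    out[[ci]] <- tibble::tibble(
      chrom = ch, pos = pos - 1,
      ref = sample(c("A", "C", "G", "T"), n_snp, replace = TRUE),
      alt = "N",
      block_id = paste0(ch, ":", block),
      hap1_allele = hap1,
      hap2_allele = ifelse(hap1 == "ref", "alt", "ref")
    )
  }
  snps <- dplyr::bind_rows(out)
  snps$alt <- ifelse(snps$ref == "A", "G", "A")
  snps
}

# sparse per-SNP allele depths: reads per haplotype proportional to local
# haplotype copy number
simulate_allele_depths <- function(cfg, snps, truth, cells, bins) {
  n_snp <- nrow(snps)
  res <- vector("list", length(cells) * 2)
  z <- 0
  for (ci in seq_along(cells)) {
    cell <- cells[ci]
    for (hap in c("1", "2")) {
      cn <- rep(1, n_snp)
      ev <- truth[truth$cell_id == cell &
                    (truth$haplotype == hap | truth$type == "HOM_DEL"), ]
      for (i in seq_len(nrow(ev))) {
        inside <- snps$chrom == ev$chrom[i] & snps$pos >= ev$start[i] &
          snps$pos < ev$end[i]
        cn[inside] <- cn[inside] + ifelse(ev$type[i] == "DUP", 1, -1)
      }
      cn <- pmax(cn, 0)
      # copy numbers at SNPs are small integers: sample per copy-number
      # class uniformly (fast) instead of one weighted draw over all SNPs
      tab <- integer(n_snp)
      for (v in setdiff(unique(cn), 0)) {
        idx <- which(cn == v)
        n_reads <- stats::rpois(1, cfg$hap_cov * v * length(idx))
        if (n_reads == 0) next
        hit <- idx[sample.int(length(idx), n_reads, replace = TRUE)]
        tab <- tab + tabulate(hit, n_snp)
      }
      nz <- which(tab > 0)
      z <- z + 1
      res[[z]] <- tibble::tibble(cell_id = cell, snp = nz, hap = hap,
                                 n = tab[nz])
    }
  }
  raw <- dplyr::bind_rows(res[seq_len(z)])
  raw$allele <- ifelse(raw$hap == "1", snps$hap1_allele[raw$snp],
                       snps$hap2_allele[raw$snp])
  # aggregate the two haplotype rows per (cell, snp) with a numeric key
  key <- (match(raw$cell_id, cells) - 1) * n_snp + raw$snp
  m <- rowsum(cbind(ref = raw$n * (raw$allele == "ref"),
                    alt = raw$n * (raw$allele == "alt")), key)
  k <- as.numeric(rownames(m))
  snp_idx <- ((k - 1) %% n_snp) + 1
  tibble::tibble(
    cell_id = cells[((k - 1) %/% n_snp) + 1],
    chrom = snps$chrom[snp_idx],
    pos = snps$pos[snp_idx],
    ref_depth = as.integer(m[, "ref"]),
    alt_depth = as.integer(m[, "alt"])
  )
}

#' Write a simulated dataset to standard-format files
#'
#' Emits the phased VCF, the cells-by-bins count TSV, the allele-depth
#' TSV, a bulk-count TSV and the truth BED into `dir`.
#'
#' @param sim A `scoval_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phased_vcf(sim$snps, file.path(dir, "phased_snps.vcf"))
  write_cell_counts(sim$counts, file.path(dir, "cell_counts.tsv"))
  write_allele_depths(sim$depths, file.path(dir, "allele_depths.tsv"))
  readr::write_tsv(tibble::tibble(bin = sim$bins$bin, count = sim$bulk),
                   file.path(dir, "bulk_counts.tsv"))
  readr::write_tsv(
    sim$truth[, c("chrom", "start", "end", "cell_id", "type", "haplotype")],
    file.path(dir, "truth.bed"), col_names = FALSE
  )
  invisible(dir)
}

#' Compare a call set to the simulator truth
#'
#' Calls and truth events match when they are in the same cell and overlap
#' reciprocally by at least `reciprocal` of each interval. Precision is
#' the fraction of calls matching some truth event; recall the fraction of
#' truth events recovered. An empty call set has undefined precision,
#' reported as 1 with `precision_defined = FALSE`.
#'
#' @param calls Call tibble.
#' @param truth Truth tibble from the simulator (`GERMLINE_DEL` rows are
#'   ignored).
#' @param reciprocal Reciprocal-overlap threshold (default 0.5).
#' @param types Truth event types to evaluate (default deletion types).
#' @return Tibble with `precision`, `recall`, `n_calls`, `n_truth`,
#'   `n_matched_calls`, `n_matched_truth`, `precision_defined`.
#' @export
compare_to_truth <- function(calls, truth, reciprocal = 0.5,
                             types = c("HET_DEL", "HOM_DEL", "MONOSOMY")) {
  tr <- truth[truth$type %in% types, ]
  match_one <- function(a_start, a_end, b_start, b_end) {
    ov <- pmin(a_end, b_end) - pmax(a_start, b_start)
    ov >= reciprocal * (a_end - a_start) &
      ov >= reciprocal * (b_end - b_start)
  }
  call_hit <- rep(FALSE, nrow(calls))
  truth_hit <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(calls))) {
    j <- which(tr$cell_id == calls$cell_id[i] &
                 tr$chrom == calls$chrom[i] &
                 match_one(calls$start[i], calls$end[i], tr$start, tr$end))
    if (length(j) > 0) {
      call_hit[i] <- TRUE
      truth_hit[j] <- TRUE
    }
  }
  prec_def <- nrow(calls) > 0
  tibble::tibble(
    precision = if (prec_def) mean(call_hit) else 1,
    recall = if (nrow(tr) > 0) mean(truth_hit) else NA_real_,
    n_calls = nrow(calls), n_truth = nrow(tr),
    n_matched_calls = sum(call_hit), n_matched_truth = sum(truth_hit),
    precision_defined = prec_def
  )
}

#' Haplotype accuracy of matched heterozygous deletion calls
#'
#' For each call, the deleted haplotype is predicted from the sign of the
#' median signed pseudocount log2 ratio over the call's internal windows
#' (haplotype 2 deleted when haplotype 1 dominates, and vice versa) and
#' compared with the planted haplotype of the overlapping truth event.
#'
#' @param calls Heterozygous deletion calls.
#' @param truth Simulator truth.
#' @param window_stats Window statistics from [count_informative_reads()].
#' @param snp_windows Result of [build_snp_windows()].
#' @param reciprocal Matching threshold (default 0.5).
#' @return Tibble with `n_scored`, `n_correct`, `accuracy`.
#' @export
haplotype_accuracy <- function(calls, truth, window_stats, snp_windows,
                               reciprocal = 0.5) {
  windows <- snp_windows$windows
  smat <- stat_matrix(window_stats, "signed_log2_pc")
  tr <- truth[truth$type == "HET_DEL", ]
  n_scored <- 0L; n_correct <- 0L
  for (i in seq_len(nrow(calls))) {
    ov <- pmin(calls$end[i], tr$end) - pmax(calls$start[i], tr$start)
    j <- which(tr$cell_id == calls$cell_id[i] &
                 tr$chrom == calls$chrom[i] &
                 ov >= reciprocal * (calls$end[i] - calls$start[i]) &
                 ov >= reciprocal * (tr$end - tr$start))
    if (length(j) == 0) next
    wid <- windows$window_id[windows$chrom == calls$chrom[i] &
                               windows$start >= calls$start[i] &
                               windows$end <= calls$end[i]]
    if (length(wid) == 0 || !calls$cell_id[i] %in% rownames(smat)) next
    s <- stats::median(smat[calls$cell_id[i], wid], na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    pred <- if (s > 0) "2" else "1"
    n_scored <- n_scored + 1L
    if (pred == tr$haplotype[j[1]]) n_correct <- n_correct + 1L
  }
  tibble::tibble(n_scored = n_scored, n_correct = n_correct,
                 accuracy = if (n_scored > 0) n_correct / n_scored
                 else NA_real_)
}
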