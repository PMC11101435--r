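test_that("breakpoint collection maps call boundaries to bins", {
  bins <- toy_bins(c(t = 3e7))
  calls <- tibble::tibble(
    cell_id = c("a", "b", "c"), chrom = "t",
    start = c(5e6, 5e6, 1.2e7),      # a and b share a start bin
    end = c(1e7, 8e6, 1.6e7)
  )
  bp <- collect_breakpoints(calls, bins)
  shared <- bp[bp$start <= 5e6 & bp$end > 5e6, ]
  expect_equal(shared$breakpoint_count, 2)
  expect_true(shared$is_cnvb)
  # an isolated call's bins are not recurrent
  solo <- bp[bp$start <= 1.2e7 & bp$end > 1.2e7, ]
  expect_equal(solo$breakpoint_count, 1)
  expect_false(solo$is_cnvb)
  # conservation: total breakpoints = 2 x calls
  expect_equal(sum(bp$breakpoint_count), 2 * nrow(calls))
  # normalization by bin width
  expect_equal(bp$normalized_count,
               bp$breakpoint_count / (bp$end - bp$start))

  # whole-chromosome deletion: breakpoints in the first and last bin
  wc <- tibble::tibble(cell_id = "w", chrom = "t", start = 0, end = 3e7)
  bpw <- collect_breakpoints(wc, bins)
  expect_equal(bpw$bin, c(1L, nrow(bins)))

  # boundary in a masked bin reassigns to the nearest unmasked bin
  bpm <- collect_breakpoints(calls[3, ], bins, masked_bins = 25L)
  expect_false(25L %in% bpm$bin)
  expect_equal(attr(bpm, "n_reassigned"), 1)
})

test_that("recurrent breakpoints exceed the permutation null", {
  set.seed(21)
  # variable mappability so bin widths vary (every other Mb unmappable in
  # part of the chromosome): size normalization has something to normalize
  mapp <- tibble::tibble(
    chrom = "a",
    start = c(seq(0, 3.9e7, by = 2e6), 4e7),
    end = c(seq(0, 3.9e7, by = 2e6) + 1.2e6, 1e8)
  )
  lay <- genome_layout(tibble::tibble(chrom = "a", length = 1e8), mapp)
  bins <- make_variable_bins(lay, 5e5)
  reg <- partition_5mb(lay)
  # ten recurrent loci with eight carrier cells each, plus scattered calls
  loci <- seq(4.2e7, 8.7e7, by = 5e6)
  rec <- tidyr::expand_grid(locus = loci, rep = 1:8)
  calls <- dplyr::bind_rows(
    tibble::tibble(cell_id = sprintf("r%03d", seq_len(nrow(rec))),
                   chrom = "a", start = rec$locus,
                   end = rec$locus + 4e6),
    tibble::tibble(cell_id = sprintf("s%02d", 1:20), chrom = "a",
                   start = floor(runif(20, 0, 8e7)), end = NA)
  )
  n <- nrow(calls)
  calls$end[(n - 19):n] <- calls$start[(n - 19):n] + runif(20, 5e6, 1.5e7)
  # plain genomic placement: wider bins then receive more random
  # breakpoints, which is what the size normalization corrects for
  null <- permute_callset(calls, lay, reg, n_perm = 30, seed = 6,
                          keep_calls = 30, mappable_space = FALSE)
  obs_bp <- collect_breakpoints(calls, bins)
  r <- breakpoint_clustering_test(obs_bp, null$perm_calls, bins)
  expect_lt(r$p_value, 1e-6)
  expect_gt(r$n_obs_cnvb, 0)
  # permuted breakpoint counts grow with bin size on average
  expect_true(is.finite(r$perm_slope))
  expect_gt(r$perm_slope, 0)
})

test_that("long-gene enrichment responds to genes planted at breakpoints", {
  set.seed(22)
  lay <- toy_layout(c(a = 1e8))
  bins <- make_variable_bins(lay, 5e5)
  reg <- partition_5mb(lay)
  calls <- tibble::tibble(cell_id = sprintf("r%02d", 1:15), chrom = "a",
                          start = 3e7, end = 4.2e7)
  null <- permute_callset(calls, lay, reg, n_perm = 20, seed = 7,
                          keep_calls = 20)
  obs_bp <- collect_breakpoints(calls, bins)
  # long genes stacked at the recurrent breakpoints
  genes <- tibble::tibble(
    chrom = "a",
    start = c(rep(2.99e7, 8), rep(4.19e7, 8), runif(10, 0, 9e7)),
    gene = sprintf("g%02d", 1:26)
  )
  genes$end <- genes$start + 2e5
  r <- long_gene_enrichment(obs_bp, null$perm_calls, bins, genes)
  expect_gt(r$fold, 0)
  expect_lt(r$p_value, 0.01)
  # threshold above every gene length: undefined
  r2 <- long_gene_enrichment(obs_bp, null$perm_calls, bins, genes,
                             threshold = 1e6)
  expect_true(is.na(r2$p_value))
})

test_that("TPM comparison contrasts longest genes at breakpoint bins", {
  set.seed(23)
  lay <- toy_layout(c(a = 1e8))
  bins <- make_variable_bins(lay, 5e5)
  reg <- partition_5mb(lay)
  calls <- tibble::tibble(cell_id = sprintf("r%02d", 1:15), chrom = "a",
                          start = 3e7, end = 4.2e7)
  null <- permute_callset(calls, lay, reg, n_perm = 20, seed = 8,
                          keep_calls = 20)
  obs_bp <- collect_breakpoints(calls, bins)
  genes <- tibble::tibble(chrom = "a", start = seq(0, 9.8e7, by = 2e6),
                          gene = sprintf("g%02d", 1:50))
  genes$end <- genes$start + 1.5e5
  # flat expression: no difference
  tpm_flat <- tibble::tibble(gene = genes$gene, tpm = 10)
  r <- tpm_comparison(obs_bp, null$perm_calls, bins, genes, tpm_flat)
  expect_gt(r$p_value, 0.2)
  # expression inflated near the recurrent breakpoints
  tpm_hot <- dplyr::mutate(tpm_flat, tpm = ifelse(
    genes$start > 2.8e7 & genes$start < 4.4e7, 100, 10
  ))
  r2 <- tpm_comparison(obs_bp, null$perm_calls, bins, genes, tpm_hot)
  expect_lt(r2$p_value, 0.05)
})

test_that("CNVRs group calls sharing both boundary bins", {
  bins <- toy_bins(c(t = 3e7))
  calls <- tibble::tibble(
    cell_id = c("a", "b", "c", "d"),
    chrom = "t",
    start = c(5e6, 5e6, 5e6, 2e7),
    end = c(1e7, 1e7, 1.5e7, 2.5e7),
    first_bin = c(11, 11, 11, 41),
    last_bin = c(20, 20, 30, 50)
  )
  cnvrs <- find_cnvrs(calls)
  expect_equal(nrow(cnvrs), 1) # only a and b share both boundary bins
  expect_equal(cnvrs$member_cells[[1]], c("a", "b"))
})

test_that("clonality classification separates shared and opposite haplotypes", {
  # construct windows inside a CNVR spanning bins 11..20
  bins <- toy_bins(c(t = 3e7))
  snps <- dplyr::bind_rows(lapply(11:20, function(b) {
    tibble::tibble(
      chrom = "t", pos = bins$start[b] + 1000 * (1:40), ref = "A",
      alt = "G", block_id = paste0("t:", b), hap1_allele = "ref",
      hap2_allele = "alt"
    )
  }))
  sw <- build_snp_windows(snps)
  wid <- sw$windows$window_id
  cnvr <- tibble::tibble(
    cnvr_id = "cnvr1", chrom = "t", start = 5e6, end = 1e7,
    first_bin = 11, last_bin = 20, n_cells = 2,
    member_cells = list(c("p", "q"))
  )
  # same haplotype lost in both members: deltas near zero
  same <- dplyr::bind_rows(
    toy_window_stats("p", wid, h1 = rpois(10, 10), h2 = 0L),
    toy_window_stats("q", wid, h1 = rpois(10, 10), h2 = 0L)
  )
  r1 <- cnvr_clonality(cnvr, same, sw, bins)
  expect_equal(r1$klass, "SHARED_HAPLOTYPE")
  expect_lt(r1$delta_median_log2, 2)

  # opposite haplotypes: (40, 1)-like counts give per-cell signed ratios
  # of about +-4.75 and a delta near 9.5
  opp <- dplyr::bind_rows(
    toy_window_stats("p", wid, h1 = 40L, h2 = 1L),
    toy_window_stats("q", wid, h1 = 1L, h2 = 40L)
  )
  r2 <- cnvr_clonality(cnvr, opp, sw, bins)
  expect_equal(r2$klass, "OPPOSITE_HAPLOTYPE")
  expect_equal(r2$delta_median_log2, 2 * log2(40.5 / 1.5))

  # a technical replicate listed twice: identical data, delta exactly 0
  cnvr_rep <- dplyr::mutate(cnvr,
                            member_cells = list(c("p", "p2")))
  rep_stats <- dplyr::bind_rows(
    toy_window_stats("p", wid, h1 = c(9, 12, 7, 11, 10, 8, 13, 9, 10, 11),
                     h2 = 0L),
    toy_window_stats("p2", wid, h1 = c(9, 12, 7, 11, 10, 8, 13, 9, 10, 11),
                     h2 = 0L)
  )
  r3 <- cnvr_clonality(cnvr_rep, rep_stats, sw, bins)
  expect_equal(r3$delta_median_log2, 0)

  # global haplotype relabeling leaves the delta unchanged
  flip <- dplyr::mutate(opp, tmp = hap1_reads, hap1_reads = hap2_reads,
                        hap2_reads = tmp)
  flip <- window_log2_ratio(flip[, c("cell_id", "window_id",
                                     "hap1_reads", "hap2_reads")])
  r4 <- cnvr_clonality(cnvr, flip, sw, bins)
  expect_equal(r4$delta_median_log2, r2$delta_median_log2)

  # fewer than two informative members: undefined
  lone <- toy_window_stats("p", wid, h1 = 10L, h2 = 0L)
  r5 <- cnvr_clonality(cnvr, lone, sw, bins)
  expect_true(is.na(r5$klass))
})

test_that("technical replicates are flagged by profile correlation", {
  set.seed(24)
  base <- rlnorm(200, 0, 0.2) * 2
  cn <- rbind(
    t1 = base * rlnorm(200, 0, 0.02),
    t2 = base * rlnorm(200, 0, 0.02),
    other = 2 * rlnorm(200, 0, 0.2)
  )
  calls <- tibble::tibble(cell_id = c("t1", "t2"), chrom = "a",
                          start = 0, end = 1e6)
  reps <- detect_technical_replicates(cn, calls, cor_threshold = 0.95)
  expect_equal(nrow(reps), 1)
  expect_equal(sort(c(reps$cell_a, reps$cell_b)), c("t1", "t2"))
  expect_true(reps$identical_calls)
})
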