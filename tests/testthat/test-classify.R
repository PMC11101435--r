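test_that("empirical LOH p value counts ties against the carrier", {
  bg <- seq(0.1, 1.0, by = 0.1)
  expect_equal(empirical_loh_pvalue(0.85, bg, min_background = 5), 0.2)
  # carrier above every background value: p is exactly 0
  expect_equal(empirical_loh_pvalue(2, bg, min_background = 5), 0)
  # carrier at the background median: p near one half (inclusive ties)
  expect_equal(empirical_loh_pvalue(0.5, bg, min_background = 5), 0.6)
  expect_warning(empirical_loh_pvalue(0.5, bg), "background")
})

test_that("LOH p values separate carriers from non-carriers in simulation", {
  res <- shared_result()
  sim <- shared_sim()
  calls <- res$calls[res$calls$type == "HET_DEL", ]
  tr <- sim$truth[sim$truth$type == "HET_DEL", ]
  is_true_call <- vapply(seq_len(nrow(calls)), function(i) {
    ov <- pmin(calls$end[i], tr$end) - pmax(calls$start[i], tr$start)
    any(tr$cell_id == calls$cell_id[i] & tr$chrom == calls$chrom[i] &
          ov >= 0.5 * (tr$end - tr$start))
  }, logical(1))
  expect_gt(sum(is_true_call), 5)
  # every truth-backed candidate is LOH-supported at the candidate level
  expect_true(all(calls$empirical_p[is_true_call] < 0.05))
})

test_that("the naive-Bayes classifier scores by class-conditional densities", {
  set.seed(13)
  cand <- rnorm(200, 2, 0.3)
  null <- rnorm(200, 0.2, 0.1)
  clf <- fit_loh_classifier(cand, null)
  expect_gt(clf$means["cnv"], clf$means["null"])
  # candidates score high, nulls low
  expect_true(all(predict(clf, cand) > 0.9))
  expect_true(all(predict(clf, null) < 0.1))
  # equidistant point between equal-weight equal-sd classes scores 0.5
  clf2 <- structure(list(means = c(cnv = 2, null = 0),
                         sds = c(cnv = 0.5, null = 0.5),
                         priors = c(cnv = 0.5, null = 0.5)),
                    class = "loh_classifier")
  expect_equal(predict(clf2, 1), 0.5)
  # refitting on the same data is deterministic
  expect_identical(fit_loh_classifier(cand, null),
                   fit_loh_classifier(cand, null))
  # identical classes carry no signal
  expect_error(fit_loh_classifier(c(1, 1, 1), c(1, 1, 1)), "identical")
})

test_that("null regions are size-matched and avoid candidate territory", {
  set.seed(14)
  lay <- toy_layout(c(a = 5e7, b = 3e7))
  calls <- tibble::tibble(
    cell_id = c("c1", "c1", "c2"), chrom = c("a", "b", "a"),
    start = c(1e7, 0, 2e7), end = c(2e7, 1e7, 2.6e7)
  )
  nulls <- make_null_regions(calls, lay, n_sets = 30, seed = 1)
  expect_equal(nrow(nulls), 90)
  expect_equal(sort(unique(nulls$end - nulls$start)), c(6e6, 1e7))
  for (i in seq_len(nrow(nulls))) {
    excl <- calls[calls$cell_id == nulls$cell_id[i], ]
    expect_false(any(excl$chrom == nulls$chrom[i] &
                       excl$start < nulls$end[i] &
                       excl$end > nulls$start[i]))
  }
})

test_that("sparse-window filter drops calls without informative windows", {
  snps <- dplyr::bind_rows(lapply(1:10, function(b) {
    tibble::tibble(
      chrom = "c1", pos = (b - 1) * 1e5 + 100 * (1:30), ref = "A",
      alt = "G", block_id = paste0("c1:", b),
      hap1_allele = "ref", hap2_allele = "alt"
    )
  }))
  sw <- build_snp_windows(snps)
  expect_equal(nrow(sw$windows), 10)
  call <- tibble::tibble(cell_id = "c1", chrom = "c1", start = 0,
                         end = 1e6)
  mk_stats <- function(reads_per_window) {
    toy_window_stats("c1", sw$windows$window_id,
                     h1 = reads_per_window, h2 = 0L)
  }
  # 8 of 10 windows below 3 reads: fraction 0.8 > 0.75, dropped
  r1 <- sparse_window_filter(call, mk_stats(c(rep(0, 8), 10, 10)), sw)
  expect_false(r1$sparse_pass)
  expect_equal(r1$sparse_fraction, 0.8)
  # all windows covered: kept
  r2 <- sparse_window_filter(call, mk_stats(rep(10, 10)), sw)
  expect_true(r2$sparse_pass)
  # exactly 75% sparse: kept (the rule is "more than 75%")
  stats75 <- toy_window_stats("c1", sw$windows$window_id[1:8],
                              h1 = c(rep(0L, 6), 10L, 10L), h2 = 0L)
  call8 <- tibble::tibble(cell_id = "c1", chrom = "c1", start = 0,
                          end = 8e5 + 1)
  r4 <- sparse_window_filter(call8, stats75, sw)
  expect_equal(r4$sparse_fraction, 0.75)
  expect_true(r4$sparse_pass)
  # no internal windows at all: dropped
  far <- tibble::tibble(cell_id = "c1", chrom = "c1", start = 5e6,
                        end = 6e6)
  r5 <- sparse_window_filter(far, mk_stats(rep(10, 10)), sw)
  expect_false(r5$sparse_pass)
  expect_true(is.na(r5$sparse_fraction))
})

test_that("read-depth ratio follows its defining identity", {
  # C = 5, B = 100, R_B = 1e6, R_i = 1e5 gives RDR 0.5
  counts <- matrix(c(5, 99995), 1, dimnames = list("c1", NULL))
  bulk <- c(100, 999900)
  expect_equal(unname(compute_rdr(counts, bulk)[1, 1]), 0.5)
  # a cell that is a scaled copy of bulk has RDR exactly 1 everywhere
  bulk2 <- c(120, 80, 200, 50)
  cell <- matrix(3 * bulk2, 1, dimnames = list("c1", NULL))
  expect_true(all(compute_rdr(cell, bulk2) == 1))
  # zero-coverage bulk bins are masked
  r <- compute_rdr(cell, c(bulk2[1:3], 0))
  expect_true(all(is.na(r[, 4])))
  # without bulk, a pseudo-bulk substitutes and is flagged
  m <- matrix(rpois(40, 50), 4, 10,
              dimnames = list(paste0("c", 1:4), NULL))
  expect_true(attr(compute_rdr(m), "pseudo_bulk"))
  expect_false(attr(compute_rdr(m, colSums(m)), "pseudo_bulk"))
})

test_that("diploid cells have mean RDR 1 within sampling error", {
  sim <- shared_sim()
  clean <- setdiff(rownames(sim$counts), unique(sim$truth$cell_id))[1:10]
  rdr <- compute_rdr(sim$counts, sim$bulk)
  for (cell in clean) {
    v <- rdr[cell, ]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - 1), 3 * se)
  }
})

test_that("RDR mixture retains homozygous and reclassifies heterozygous", {
  set.seed(15)
  bins <- toy_bins(c(t = 5e7))
  mk_call <- function(cell, first, last, type, p) tibble::tibble(
    cell_id = cell, chrom = "t", start = bins$start[first],
    end = bins$end[last], type = type, first_bin = first,
    last_bin = last, empirical_p = p, status = "RAW"
  )
  # RDR matrix: hom calls near 0.03, het calls near 0.5, one provisional
  # hom at 0.48 with strong LOH support
  cells <- sprintf("c%02d", 1:21)
  rdr <- matrix(1, 21, nrow(bins), dimnames = list(cells, NULL))
  calls <- list()
  for (i in 1:10) { # het training calls
    rdr[i, 10:19] <- rnorm(10, 0.5, 0.03)
    calls[[i]] <- mk_call(cells[i], 10, 19, "HET_DEL", 0.001)
  }
  for (i in 11:20) { # hom candidates
    rdr[i, 30:39] <- rnorm(10, 0.03, 0.01)
    calls[[i]] <- mk_call(cells[i], 30, 39, "HOM_DEL", 0.5)
  }
  rdr[21, 50:59] <- rnorm(10, 0.48, 0.03) # mislabeled hom, really het
  calls[[21]] <- mk_call(cells[21], 50, 59, "HOM_DEL", 0.001)
  calls <- dplyr::bind_rows(calls)
  out <- classify_homdels(calls, rdr)
  hom <- out[out$cell_id %in% cells[11:20], ]
  expect_true(all(hom$status == "VALIDATED"))
  expect_true(all(hom$rdr_posterior > 0.99))
  re <- out[out$cell_id == cells[21], ]
  expect_equal(re$type, "HET_DEL")
  expect_equal(re$status, "RECLASSIFIED")

  # with fewer than 5 hom candidates the fixed threshold applies
  few <- calls[c(1:10, 11, 21), ]
  expect_warning(out2 <- classify_homdels(few, rdr), "fixed RDR")
  expect_equal(out2$status[out2$cell_id == cells[11]], "VALIDATED")
})

test_that("duplication assessment reports and never validates", {
  # identical distributions: p is uniform-ish, averaging near 0.5
  set.seed(16)
  ps <- replicate(200, {
    assess_duplications(rnorm(30, 0.3, 0.1), rnorm(30, 0.3, 0.1))$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  # at high window coverage a real one-haplotype gain is detectable
  set.seed(17)
  h1 <- rpois(300, 40); h2 <- rpois(300, 20) # CN 3: 2 vs 1 copies at 20x
  dup_stats <- window_log2_ratio(tibble::tibble(
    cell_id = "c", window_id = paste0("d", 1:300),
    hap1_reads = h1, hap2_reads = h2
  ))
  eu <- window_log2_ratio(tibble::tibble(
    cell_id = "c", window_id = paste0("e", 1:300),
    hap1_reads = rpois(300, 30), hap2_reads = rpois(300, 30)
  ))
  r <- assess_duplications(dup_stats$abs_log2, eu$abs_log2)
  expect_lt(r$p_value, 0.05)
  # degenerate groups are undefined
  expect_true(is.na(assess_duplications(numeric(0), rnorm(5))$p_value))
})

test_that("final assembly applies the validation rules and precedence", {
  base <- tibble::tibble(
    cell_id = c("a", "a", "b", "c", "d"),
    chrom = "t",
    start = c(0, 2e6, 0, 0, 0),
    end = c(10e6, 4e6, 5e6, 5e6, 5e6),
    type = c("HET_DEL", "HOM_DEL", "HET_DEL", "HET_DEL", "DUP"),
    empirical_p = c(0.001, 0.001, 0.5, 0.001, NA),
    nb_posterior = c(0.999, NA, 0.999, 0.5, NA),
    sparse_pass = c(TRUE, TRUE, TRUE, TRUE, NA),
    status = c("CANDIDATE", "VALIDATED", "CANDIDATE", "CANDIDATE", "RAW")
  )
  out <- assemble_final_calls(base, n_cells = 100)
  expect_equal(sort(unique(out$cell_id)), c("a"))
  expect_equal(nrow(out), 2)
  # the hom call nested in the same cell's het flank is flagged
  expect_true(out$nested_in_het[out$type == "HOM_DEL"])
  g <- glance(out)
  expect_equal(g$n_cnv_cells, 1)
  expect_equal(g$pct_cnv_cells, 1)

  # raising the posterior threshold never adds calls
  loose <- assemble_final_calls(base, 100, posterior_cutoff = 0.9)
  strict <- assemble_final_calls(base, 100, posterior_cutoff = 0.9999)
  expect_true(nrow(strict) <= nrow(loose))
  key <- function(x) paste(x$cell_id, x$start, x$end)
  expect_true(all(key(strict) %in% key(loose)))

  # empty input: empty output, zero CNV cells
  empty <- assemble_final_calls(base[0, ], n_cells = 10)
  expect_equal(nrow(empty), 0)
  expect_equal(glance(empty)$n_cnv_cells, 0)
})
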