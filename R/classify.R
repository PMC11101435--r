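#' Empirical LOH p value for one call
#'
#' The carrier statistic (median pseudocount `|log2|` allele ratio over the
#' windows inside the call, in the carrier cell) is ranked against the same
#' statistic computed in non-carrier cells over the same windows:
#' `p = #(background >= carrier) / #background`. Ties count against the
#' carrier (inclusive `>=`); `p = 0` is representable.
#'
#' @param carrier_stat Carrier cell's median statistic.
#' @param background_stats Numeric vector of non-carrier statistics.
#' @param min_background Warn below this many background cells (default 50).
#' @return Empirical p value in `[0, 1]`.
#' @export
empirical_loh_pvalue <- function(carrier_stat, background_stats,
                                 min_background = 50) {
  background_stats <- background_stats[is.finite(background_stats)]
  if (length(background_stats) < min_background) {
    warning("only ", length(background_stats),
            " background cells; empirical p is coarse")
  }
  mean(background_stats >= carrier_stat)
}

#' Empirical LOH p values for a call set
#'
#' Applies [empirical_loh_pvalue()] to every call: the background for a call
#' is every cell that has no overlapping deletion call in the same region,
#' evaluated over the call's internal windows.
#'
#' @param calls Raw call tibble (from [call_raw_cnvs()]).
#' @param window_stats Window statistics from [count_informative_reads()].
#' @param snp_windows Result of [build_snp_windows()].
#' @param min_background Warn threshold (default 50).
#' @return `calls` with added `carrier_stat`, `empirical_p`, `n_windows`,
#'   `n_background`.
#' @export
loh_pvalues <- function(calls, window_stats, snp_windows,
                        min_background = 50) {
  wmat <- stat_matrix(window_stats, "abs_log2_pc")
  windows <- snp_windows$windows
  n <- nrow(calls)
  carrier <- emp_p <- nw <- nb <- rep(NA_real_, n)
  warn_low <- FALSE
  for (i in seq_len(n)) {
    wid <- windows$window_id[windows$chrom == calls$chrom[i] &
                               windows$start >= calls$start[i] &
                               windows$end <= calls$end[i]]
    nw[i] <- length(wid)
    if (length(wid) == 0) next
    if (!calls$cell_id[i] %in% rownames(wmat)) next
    sub <- wmat[, wid, drop = FALSE]
    med <- apply(sub, 1, stats::median, na.rm = TRUE)
    carrier[i] <- med[calls$cell_id[i]]
    # background: cells without an overlapping deletion call here
    carriers_here <- unique(calls$cell_id[
      calls$chrom == calls$chrom[i] &
        calls$start < calls$end[i] & calls$end > calls$start[i] &
        calls$type %in% c("HET_DEL", "HOM_DEL")
    ])
    bg <- med[setdiff(rownames(wmat), carriers_here)]
    nb[i] <- length(bg)
    if (length(bg) < min_background) warn_low <- TRUE
    emp_p[i] <- mean(bg >= carrier[i])
  }
  if (warn_low) {
    warning("some calls had fewer than ", min_background,
            " background cells")
  }
  dplyr::mutate(calls, carrier_stat = carrier, empirical_p = emp_p,
                n_windows = nw, n_background = nb)
}

# cells x windows matrix of one window statistic
stat_matrix <- function(window_stats, stat) {
  wide <- tidyr::pivot_wider(
    window_stats[, c("cell_id", "window_id", stat)],
    names_from = "window_id", values_from = dplyr::all_of(stat)
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$cell_id
  m
}

#' Place size-matched null regions for classifier training
#'
#' For each candidate call, `n_sets` intervals of the same length are placed
#' uniformly at random in the same cell's autosomes, excluding candidate
#' territory (rejection sampling).
#'
#' @param calls Candidate call tibble.
#' @param layout A [genome_layout()].
#' @param n_sets Null sets per call (default 100).
#' @param seed Optional RNG seed.
#' @param max_tries Rejection-sampling cap per placement (default 1000).
#' @param exclude Intervals to avoid, per cell (default: `calls` itself).
#' @return Tibble `cell_id`, `chrom`, `start`, `end`, `set`.
#' @export
make_null_regions <- function(calls, layout, n_sets = 100, seed = NULL,
                              max_tries = 1000, exclude = calls) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- layout$chromosomes
  out <- vector("list", nrow(calls) * n_sets)
  z <- 0
  for (i in seq_len(nrow(calls))) {
    len <- calls$end[i] - calls$start[i]
    fit <- chroms[chroms$length >= len, ]
    if (nrow(fit) == 0) stop("call longer than every chromosome")
    excl <- exclude[exclude$cell_id == calls$cell_id[i], ]
    for (s in seq_len(n_sets)) {
      for (t in seq_len(max_tries)) {
        ch <- fit$chrom[sample.int(nrow(fit), 1,
                                   prob = fit$length - len + 1)]
        st <- floor(stats::runif(1, 0,
                                 fit$length[fit$chrom == ch] - len + 1))
        hit <- any(excl$chrom == ch & excl$start < st + len &
                     excl$end > st)
        if (!hit) break
      }
      z <- z + 1
      out[[z]] <- tibble::tibble(cell_id = calls$cell_id[i], chrom = ch,
                                 start = st, end = st + len, set = s)
    }
  }
  dplyr::bind_rows(out[seq_len(z)])
}

#' Fit the naive-Bayes LOH classifier
#'
#' Two Gaussians over the median `|log2|` allele-ratio statistic: one for
#' the CNV (LOH) class, estimated from the candidate calls, and one for the
#' non-CNV class, estimated from size-matched permuted null regions; class
#' priors come from the group sizes. The classifier returns the posterior
#' probability that a region belongs to the CNV class.
#'
#' @param candidate_stats Median statistics of candidate calls.
#' @param null_stats Median statistics of permuted non-CNV regions.
#' @return A `loh_classifier` (list with class means, sds, priors).
#' @export
fit_loh_classifier <- function(candidate_stats, null_stats) {
  candidate_stats <- candidate_stats[is.finite(candidate_stats)]
  null_stats <- null_stats[is.finite(null_stats)]
  stopifnot(length(candidate_stats) >= 2, length(null_stats) >= 2)
  m <- c(cnv = mean(candidate_stats), null = mean(null_stats))
  s <- pmax(c(cnv = stats::sd(candidate_stats),
              null = stats::sd(null_stats)), 1e-6)
  if (abs(m["cnv"] - m["null"]) < 1e-8) {
    stop("CNV and non-CNV classes have identical means; no LOH signal")
  }
  if (m["cnv"] < m["null"]) {
    warning("candidate LOH statistics are lower than null statistics; ",
            "classifier is fitted but likely meaningless")
  }
  prior <- c(cnv = length(candidate_stats), null = length(null_stats))
  prior <- prior / sum(prior)
  structure(list(means = m, sds = s, priors = prior),
            class = "loh_classifier")
}

#' @export
#' @rdname fit_loh_classifier
#' @param object A `loh_classifier`.
#' @param newdata Numeric vector of median statistics to score.
#' @param ... Unused.
predict.loh_classifier <- function(object, newdata, ...) {
  d_cnv <- object$priors["cnv"] *
    stats::dnorm(newdata, object$means["cnv"], object$sds["cnv"])
  d_null <- object$priors["null"] *
    stats::dnorm(newdata, object$means["null"], object$sds["null"])
  unname(d_cnv / (d_cnv + d_null))
}

#' @export
tidy.loh_classifier <- function(x, ...) {
  tibble::tibble(class = names(x$means), mean = unname(x$means),
                 sd = unname(x$sds), prior = unname(x$priors))
}

#' Sparse-window filter
#'
#' Excludes deletion calls whose internal phased-SNP windows are too poorly
#' covered to support an LOH verdict: a call is dropped when more than
#' `frac` of its internal windows contain fewer than `min_reads` informative
#' reads, or when it contains no window at all.
#'
#' @param calls Call tibble.
#' @param window_stats Window statistics from [count_informative_reads()].
#' @param snp_windows Result of [build_snp_windows()].
#' @param frac Sparse fraction above which a call is dropped, strict
#'   inequality (default 0.75).
#' @param min_reads Informative reads below which a window is sparse
#'   (default 3).
#' @return `calls` with added `sparse_fraction` and `sparse_pass`
#'   (`FALSE` also when there is no internal window).
#' @export
sparse_window_filter <- function(calls, window_stats, snp_windows,
                                 frac = 0.75, min_reads = 3) {
  windows <- snp_windows$windows
  tot <- window_stats$hap1_reads + window_stats$hap2_reads
  names(tot) <- paste(window_stats$cell_id, window_stats$window_id)
  sf <- rep(NA_real_, nrow(calls))
  pass <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    wid <- windows$window_id[windows$chrom == calls$chrom[i] &
                               windows$start >= calls$start[i] &
                               windows$end <= calls$end[i]]
    if (length(wid) == 0) next
    reads <- tot[paste(calls$cell_id[i], wid)]
    reads[is.na(reads)] <- 0
    sf[i] <- mean(reads < min_reads)
    pass[i] <- sf[i] <= frac
  }
  dplyr::mutate(calls, sparse_fraction = sf, sparse_pass = pass)
}

#' Read-depth ratio of single cells against bulk
#'
#' `RDR[b, i] = (C[b, i] / B[b]) * (R_B / R_i)` where `C` are single-cell
#' bin counts, `B` bulk bin counts, and `R_i`, `R_B` the respective totals.
#' An RDR near 1 is diploid, near 0.5 heterozygously deleted, near 0
#' homozygously deleted. Bins with zero bulk coverage are `NA`.
#'
#' @param counts Cell-by-bin count matrix.
#' @param bulk Bulk per-bin counts; when `NULL` a pseudo-bulk (column sums
#'   over cells) is substituted and flagged via the `pseudo_bulk` attribute.
#' @return Matrix of RDR values (cells x bins).
#' @export
compute_rdr <- function(counts, bulk = NULL) {
  pseudo <- is.null(bulk)
  if (pseudo) bulk <- colSums(counts)
  stopifnot(length(bulk) == ncol(counts))
  r_b <- sum(bulk)
  r_i <- unname(rowSums(counts))
  rdr <- sweep(counts, 2, bulk, "/") * (r_b / r_i)
  rdr[, bulk == 0] <- NA_real_
  attr(rdr, "pseudo_bulk") <- pseudo
  rdr
}

#' Arbitrate homozygous-deletion candidates by read-depth ratio
#'
#' Both haplotypes are absent in a homozygous deletion, so allele ratios
#' cannot support it; instead its cell-versus-bulk read-depth ratio should
#' sit near 0 (versus ~0.5 for heterozygous deletions). A two-component
#' Gaussian mixture is trained on the mean RDR of the LOH-validated
#' heterozygous deletions plus the provisional homozygous candidates; a
#' candidate is retained when its posterior for the low-RDR class exceeds
#' `posterior_cutoff`. A candidate whose posterior favours the
#' heterozygous class and whose LOH profile matches a heterozygous deletion
#' (`empirical_p < het_p`) is reclassified `HET_DEL`; other rejected
#' candidates are excluded. With fewer than `min_homdels` candidates the
#' mixture is not estimable and a fixed RDR threshold is applied instead.
#'
#' @param calls Call tibble containing provisional `HOM_DEL` rows and
#'   validated `HET_DEL` rows, with `empirical_p` present.
#' @param rdr RDR matrix from [compute_rdr()].
#' @param posterior_cutoff Retention cutoff (default 0.99).
#' @param het_p Empirical-p cutoff for reclassification (default 0.05).
#' @param min_homdels Minimum candidates for the mixture (default 5).
#' @param rdr_fallback Fixed threshold fallback (default 0.25).
#' @return `calls` with `rdr_mean` and, for `HOM_DEL` rows, `rdr_posterior`
#'   plus updated `type`/`status` (`VALIDATED`, `RECLASSIFIED`,
#'   `EXCLUDED`).
#' @export
classify_homdels <- function(calls, rdr, posterior_cutoff = 0.99,
                             het_p = 0.05, min_homdels = 5,
                             rdr_fallback = 0.25) {
  mean_rdr <- vapply(seq_len(nrow(calls)), function(i) {
    v <- rdr[calls$cell_id[i], calls$first_bin[i]:calls$last_bin[i]]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  calls$rdr_mean <- mean_rdr
  if (!"rdr_posterior" %in% names(calls)) calls$rdr_posterior <- NA_real_
  hom <- which(calls$type == "HOM_DEL")
  het <- which(calls$type == "HET_DEL")
  if (length(hom) == 0) return(calls)
  if (length(hom) < min_homdels) {
    warning("fewer than ", min_homdels, " homozygous candidates; using ",
            "fixed RDR threshold ", rdr_fallback)
    post <- as.numeric(calls$rdr_mean[hom] < rdr_fallback)
  } else {
    train <- c(calls$rdr_mean[het], calls$rdr_mean[hom])
    fit <- fit_gmm_1d(train[is.finite(train)], init_means = c(0, 0.5))
    lo <- which.min(fit$means)
    if (fit$means[lo] >= fit$means[-lo]) {
      stop("degenerate RDR mixture (identical means)")
    }
    post <- gmm_posterior(fit, calls$rdr_mean[hom], component = lo)
  }
  calls$rdr_posterior[hom] <- post
  keep <- post > posterior_cutoff
  reclass <- !keep & post < 0.5 &
    !is.na(calls$empirical_p[hom]) & calls$empirical_p[hom] < het_p
  calls$status[hom][keep] <- "VALIDATED"
  calls$type[hom][reclass] <- "HET_DEL"
  calls$status[hom][reclass] <- "RECLASSIFIED"
  calls$status[hom][!keep & !reclass] <- "EXCLUDED"
  calls
}

#' Assess duplication candidates against euploid background
#'
#' Compares the strict `|log2|` allele-ratio statistics of windows inside
#' duplication calls with those of size-matched euploid regions sampled
#' from the same cells, by a one-tailed Welch t-test (alternative:
#' duplications > euploid). At typical single-cell coverage this evidence
#' is weak, so duplications are reported, never promoted to the final set.
#'
#' @param dup_values Strict `abs_log2` window values inside duplications.
#' @param euploid_values Strict `abs_log2` window values in matched euploid
#'   regions.
#' @return Tibble with `statistic`, `p_value`, `n_dup`, `n_euploid`
#'   (one row; `NA` when a group has fewer than 2 values).
#' @export
assess_duplications <- function(dup_values, euploid_values) {
  dup_values <- dup_values[is.finite(dup_values)]
  euploid_values <- euploid_values[is.finite(euploid_values)]
  if (length(dup_values) < 2 || length(euploid_values) < 2) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n_dup = length(dup_values),
                          n_euploid = length(euploid_values)))
  }
  tt <- stats::t.test(dup_values, euploid_values, alternative = "greater")
  tibble::tibble(statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n_dup = length(dup_values),
                 n_euploid = length(euploid_values))
}

#' Assemble the final deletion call set
#'
#' A heterozygous deletion is VALIDATED when its empirical LOH p value is
#' below `final_p`, its classifier posterior exceeds `posterior_cutoff` and
#' it passes the sparse-window filter; homozygous deletions enter the final
#' set when retained by the RDR model; duplications are always excluded
#' from the final deletion set. A homozygous call overlapping a same-cell
#' heterozygous call is kept as a nested record and flagged.
#'
#' @param calls Call tibble carrying `empirical_p`, `nb_posterior`,
#'   `sparse_pass`, `status` (HOM rows already arbitrated by
#'   [classify_homdels()]).
#' @param n_cells Number of QC-passing cells (for the summary).
#' @param final_p Final empirical-p rule (default 0.01).
#' @param posterior_cutoff Classifier posterior rule (default 0.99).
#' @return A `scoval_callset`: tibble of final calls (with
#'   `nested_in_het`), attribute `attrition` (per-stage counts tibble) and
#'   `cnv_cells` (cells with at least one final call).
#' @export
assemble_final_calls <- function(calls, n_cells, final_p = 0.01,
                                 posterior_cutoff = 0.99) {
  if (nrow(calls) == 0) {
    out <- dplyr::mutate(calls, nested_in_het = logical(0))
  } else {
    het_ok <- calls$type == "HET_DEL" &
      !is.na(calls$empirical_p) & calls$empirical_p < final_p &
      !is.na(calls$nb_posterior) & calls$nb_posterior > posterior_cutoff &
      calls$sparse_pass
    hom_ok <- calls$type == "HOM_DEL" & calls$status == "VALIDATED"
    final <- calls[het_ok | hom_ok, ]
    final$status <- "VALIDATED"
    nested <- vapply(seq_len(nrow(final)), function(i) {
      final$type[i] == "HOM_DEL" && any(
        final$type == "HET_DEL" & final$cell_id == final$cell_id[i] &
          final$chrom == final$chrom[i] &
          final$start < final$end[i] & final$end > final$start[i]
      )
    }, logical(1))
    out <- dplyr::mutate(final, nested_in_het = nested)
  }
  counts_by <- function(f) if (nrow(calls)) sum(f) else 0L
  attrition <- tibble::tibble(
    stage = c("raw", "raw_het_del", "raw_hom_del", "raw_dup",
              "loh_p_final", "posterior_pass", "sparse_pass",
              "hom_retained", "final", "cnv_cells"),
    n = c(
      nrow(calls),
      counts_by(calls$type == "HET_DEL"),
      counts_by(calls$type == "HOM_DEL"),
      counts_by(calls$type == "DUP"),
      counts_by(calls$type == "HET_DEL" &
                  !is.na(calls$empirical_p) & calls$empirical_p < final_p),
      counts_by(calls$type == "HET_DEL" & !is.na(calls$nb_posterior) &
                  calls$nb_posterior > posterior_cutoff),
      counts_by(calls$type == "HET_DEL" & isTRUE_v(calls$sparse_pass)),
      counts_by(calls$type == "HOM_DEL" & calls$status == "VALIDATED"),
      nrow(out),
      dplyr::n_distinct(out$cell_id)
    )
  )
  structure(out, attrition = attrition, n_cells = n_cells,
            class = c("scoval_callset", class(out)))
}

isTRUE_v <- function(x) !is.na(x) & x

#' @export
glance.scoval_callset <- function(x, ...) {
  a <- attr(x, "attrition")
  tibble::tibble(
    n_final = a$n[a$stage == "final"],
    n_cnv_cells = a$n[a$stage == "cnv_cells"],
    n_cells = attr(x, "n_cells"),
    pct_cnv_cells = pct(a$n[a$stage == "cnv_cells"], attr(x, "n_cells"))
  )
}
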