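#' Permute a call set uniformly in mappable autosome space
#'
#' Generates the null model for hotspot/cold-spot detection: in each
#' permutation, every cell's CNVs are re-placed uniformly at random in the
#' autosomes while prohibiting intra-cell collision, preserving each call's
#' length and each cell's call count exactly. Placement happens in
#' concatenated mappable coordinates (masked territory removed first, so a
#' placed call may straddle removed gaps when mapped back to the genome);
#' set `mappable_space = FALSE` for plain whole-autosome placement. Hits
#' per 5 Mb region (a call counts once in every region it overlaps) are
#' recorded per permutation.
#'
#' @param calls Final call tibble (`cell_id`, `chrom`, `start`, `end`).
#' @param layout A [genome_layout()].
#' @param regions 5 Mb region tibble from [partition_5mb()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional RNG seed.
#' @param masked Optional tibble of masked intervals (`chrom`, `start`,
#'   `end`) removed from the placement space (e.g. outlier-bin territory).
#' @param mappable_space Place in concatenated mappable coordinates
#'   (default `TRUE`).
#' @param max_tries Placement attempts per cell before erroring (default
#'   1000).
#' @param keep_calls Number of permutations whose placed call tibbles are
#'   retained (default 20) for downstream breakpoint / feature
#'   comparisons.
#' @return A `scoval_null`: list with `null_hits` (regions x permutations
#'   integer matrix), `observed` (vector of observed hits), `regions`, and
#'   `perm_calls` (list of the first `keep_calls` permuted call tibbles,
#'   with `cell_id` preserved).
#' @export
permute_callset <- function(calls, layout, regions, n_perm = 10000,
                            seed = NULL, masked = NULL,
                            mappable_space = TRUE, max_tries = 1000,
                            keep_calls = 20) {
  if (!is.null(seed)) set.seed(seed)
  space <- if (mappable_space) layout$mappable else
    tibble::tibble(chrom = layout$chromosomes$chrom, start = 0,
                   end = layout$chromosomes$length)
  if (!is.null(masked) && nrow(masked) > 0) {
    space <- subtract_intervals(space, merge_intervals(masked))
  }
  segs <- split(space, space$chrom)
  minfo <- lapply(segs, function(s) {
    w <- s$end - s$start
    list(s = s, cum = cumsum(w), total = sum(w))
  })
  chrom_tot <- vapply(minfo, `[[`, numeric(1), "total")
  # mappable-space length of each observed call
  mlen <- vapply(seq_len(nrow(calls)), function(i) {
    interval_overlap_bp(calls$chrom[i], calls$start[i], calls$end[i], space)
  }, numeric(1))
  mlen <- pmax(mlen, 1)
  by_cell <- split(seq_len(nrow(calls)), calls$cell_id)
  observed <- count_region_hits(calls, regions)
  null_hits <- matrix(0L, nrow(regions), n_perm)
  perm_calls <- vector("list", min(keep_calls, n_perm))
  for (p in seq_len(n_perm)) {
    placed <- place_cells(by_cell, mlen, minfo, chrom_tot, max_tries)
    null_hits[, p] <- count_region_hits(placed, regions)
    if (p <= keep_calls) {
      placed$cell_id <- calls$cell_id
      perm_calls[[p]] <- placed
    }
  }
  structure(
    list(null_hits = null_hits, observed = observed, regions = regions,
         perm_calls = perm_calls),
    class = "scoval_null"
  )
}

# place every cell's calls without intra-cell overlap; returns a call
# tibble. Vectorized: all calls are drawn at once, then cells whose calls
# collide are redrawn until clean.
place_cells <- function(by_cell, mlen, minfo, chrom_tot, max_tries) {
  chroms <- names(chrom_tot)
  n <- length(mlen)
  if (any(mlen > max(chrom_tot))) {
    stop("call longer than every chromosome's space")
  }
  cell_of <- integer(n)
  for (k in seq_along(by_cell)) cell_of[by_cell[[k]]] <- k
  multi <- which(lengths(by_cell) > 1)
  ch_idx <- integer(n)
  s <- numeric(n)
  todo <- seq_len(n)
  for (t in seq_len(max_tries)) {
    # per-call chromosome weights: valid placement measure per chromosome
    w <- pmax(outer(rep(1, length(todo)), chrom_tot) - mlen[todo] + 1, 0)
    cum <- w %*% upper.tri(diag(ncol(w)), diag = TRUE)
    u <- stats::runif(length(todo)) * cum[, ncol(cum)]
    pick <- rowSums(u > cum) + 1L
    ch_idx[todo] <- pick
    s[todo] <- floor(stats::runif(length(todo)) *
                       (chrom_tot[pick] - mlen[todo] + 1))
    # redraw cells with intra-cell collisions
    bad <- integer(0)
    for (k in multi) {
      ii <- by_cell[[k]]
      o <- order(ch_idx[ii], s[ii])
      ii <- ii[o]
      coll <- any(ch_idx[ii][-1] == ch_idx[ii][-length(ii)] &
                    s[ii][-1] < s[ii][-length(ii)] +
                      mlen[ii][-length(ii)])
      if (coll) bad <- c(bad, by_cell[[k]])
    }
    todo <- bad
    if (length(todo) == 0) break
    if (t == max_tries) {
      stop("could not place a cell's CNVs without collision after ",
           max_tries, " attempts")
    }
  }
  out_start <- out_end <- numeric(n)
  for (c in unique(ch_idx)) {
    ii <- which(ch_idx == c)
    out_start[ii] <- mappable_to_genomic(chroms[c], s[ii], minfo)
    out_end[ii] <- mappable_to_genomic(chroms[c], s[ii] + mlen[ii], minfo)
  }
  tibble::tibble(chrom = chroms[ch_idx], start = out_start, end = out_end)
}

# inverse of the concatenated-mappable-coordinate map
mappable_to_genomic <- function(chrom, mpos, minfo) {
  mi <- minfo[[chrom]]
  idx <- findInterval(mpos, mi$cum, left.open = TRUE) + 1
  idx <- pmin(idx, nrow(mi$s))
  prev <- c(0, mi$cum)[idx]
  mi$s$start[idx] + (mpos - prev)
}

# remove interval set b (disjoint) from interval set a (disjoint)
subtract_intervals <- function(a, b) {
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    cuts <- b[b$chrom == a$chrom[i] & b$start < a$end[i] &
                b$end > a$start[i], ]
    if (nrow(cuts) == 0) {
      out[[i]] <- a[i, c("chrom", "start", "end")]
      next
    }
    cuts <- dplyr::arrange(cuts, .data$start)
    starts <- c(a$start[i], pmin(cuts$end, a$end[i]))
    ends <- c(pmax(cuts$start, a$start[i]), a$end[i])
    keep <- starts < ends
    out[[i]] <- tibble::tibble(chrom = a$chrom[i], start = starts[keep],
                               end = ends[keep])
  }
  dplyr::bind_rows(out)
}

# hits per region: number of calls overlapping each region (vectorized
# index arithmetic: regions tile from 0 per chromosome)
count_region_hits <- function(calls, regions) {
  hits <- integer(nrow(regions))
  if (nrow(calls) == 0) return(hits)
  rsize <- regions$end[1] - regions$start[1]
  first_region <- tapply(regions$region, regions$chrom, min)
  n_regions <- tapply(regions$region, regions$chrom, length)
  m <- match(calls$chrom, names(first_region))
  ok <- !is.na(m)
  lo <- pmax(floor(calls$start[ok] / rsize), 0)
  hi <- pmin(floor((calls$end[ok] - 1) / rsize),
             as.numeric(n_regions)[m[ok]] - 1)
  span <- hi - lo + 1
  keep <- span > 0
  idx <- rep(as.numeric(first_region)[m[ok]][keep] + lo[keep],
             span[keep]) + sequence(span[keep]) - 1
  tabulate(idx, nbins = nrow(regions))
}

#' Empirical region p values and hotspot / cold-spot classification
#'
#' For each region, `p` is the fraction of permutations whose hit count was
#' at least as high as the observed count (raw fraction, no pseudocount).
#' Regions with `p < hot_p` are hotspots (observed hits in the null's upper
#' tail); regions with `p > cold_p` are cold spots (nearly every
#' permutation matched or exceeded the observation). The cold cutoff is
#' deliberately more stringent because discrete low counts make the lower
#' extreme liberal.
#'
#' @param null A `scoval_null` from [permute_callset()] (or a list with
#'   `null_hits`, `observed`, `regions`).
#' @param hot_p Hotspot cutoff (default 0.05).
#' @param cold_p Cold-spot cutoff (default 0.99).
#' @return Tibble of `RegionStat`s: region columns plus `observed_hits`,
#'   `null_mean`, `p_value`, `klass` (`HOT`/`COLD`/`CONTROL`).
#' @export
region_pvalues <- function(null, hot_p = 0.05, cold_p = 0.99) {
  p <- rowMeans(null$null_hits >= null$observed)
  dplyr::mutate(
    null$regions,
    observed_hits = null$observed,
    null_mean = rowMeans(null$null_hits),
    p_value = p,
    klass = dplyr::case_when(p < hot_p ~ "HOT", p > cold_p ~ "COLD",
                             TRUE ~ "CONTROL")
  )
}

#' Screen cold spots for artifact overlap
#'
#' A cold spot could simply be territory where calling is impossible.
#' Cold regions are coordinate-merged, then each merged spot's overlap (bp)
#' with the union of removed bad-bin territory and blacklist regions is
#' compared against `n_rand` equal-length intervals placed uniformly in the
#' autosomes outside cold spots. A spot whose artifact overlap lies in the
#' upper `alpha` tail of the random intervals is removed
#' (`klass = COLD_REMOVED`).
#'
#' @param region_stats Region tibble from [region_pvalues()].
#' @param bad_bins Tibble of removed bad-bin intervals (or `NULL`).
#' @param blacklist Tibble of blacklist intervals (or `NULL`).
#' @param layout A [genome_layout()].
#' @param n_rand Random intervals per spot (default 1000).
#' @param alpha Removal tail (default 0.05).
#' @param seed Optional RNG seed.
#' @return Tibble of merged cold spots with `artifact_bp`, `p_artifact`,
#'   `removed`.
#' @export
screen_cold_spots <- function(region_stats, bad_bins = NULL,
                              blacklist = NULL, layout, n_rand = 1000,
                              alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cold <- region_stats[region_stats$klass == "COLD", ]
  spots <- merge_intervals(cold)
  if (nrow(spots) == 0) return(dplyr::mutate(spots, artifact_bp = numeric(0),
                                             p_artifact = numeric(0),
                                             removed = logical(0)))
  art <- dplyr::bind_rows(bad_bins, blacklist)
  if (nrow(art) == 0 || is.null(art)) {
    warning("no bad-bin or blacklist input; all cold spots retained")
    return(dplyr::mutate(spots, artifact_bp = 0, p_artifact = 1,
                         removed = FALSE))
  }
  art <- merge_intervals(art)
  chroms <- layout$chromosomes
  obs_bp <- p_art <- numeric(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    L <- spots$end[i] - spots$start[i]
    obs_bp[i] <- interval_overlap_bp(spots$chrom[i], spots$start[i],
                                     spots$end[i], art)
    fit <- chroms[chroms$length >= L, ]
    rnd <- numeric(n_rand)
    for (r in seq_len(n_rand)) {
      repeat {
        ch <- fit$chrom[sample.int(nrow(fit), 1,
                                   prob = fit$length - L + 1)]
        s <- floor(stats::runif(1, 0, fit$length[fit$chrom == ch] - L + 1))
        inside_cold <- any(spots$chrom == ch & spots$start < s + L &
                             spots$end > s)
        if (!inside_cold) break
      }
      rnd[r] <- interval_overlap_bp(ch, s, s + L, art)
    }
    p_art[i] <- mean(rnd >= obs_bp[i])
  }
  dplyr::mutate(spots, artifact_bp = obs_bp, p_artifact = p_art,
                removed = p_art < alpha)
}

#' Feature density contrasts between region classes
#'
#' Counts features (genes, open-chromatin peaks, pathogenic-CNV regions...)
#' overlapping each region and contrasts hotspot and cold-spot totals
#' against control regions with a chi-square test using region counts as
#' exposure.
#'
#' @param region_stats Region tibble from [region_pvalues()] (optionally
#'   after cold-spot screening).
#' @param features Tibble of feature intervals (`chrom`, `start`, `end`).
#' @return List with `per_class` (tibble: class, n_regions, total, mean,
#'   sd) and `tests` (tibble: contrast, statistic, p_value; contrasts with
#'   an empty class or zero features are skipped).
#' @export
region_feature_density <- function(region_stats, features) {
  rs <- dplyr::mutate(region_stats,
                      n_feat = count_overlaps(region_stats, features))
  per_class <- rs |>
    dplyr::group_by(klass = .data$klass) |>
    dplyr::summarise(n_regions = dplyr::n(), total = sum(.data$n_feat),
                     mean = mean(.data$n_feat), sd = stats::sd(.data$n_feat),
                     .groups = "drop")
  tests <- list()
  for (cls in c("HOT", "COLD")) {
    a <- per_class[per_class$klass == cls, ]
    b <- per_class[per_class$klass == "CONTROL", ]
    if (nrow(a) == 0 || nrow(b) == 0 || a$total + b$total == 0) next
    ct <- stats::chisq.test(
      x = c(a$total, b$total),
      p = c(a$n_regions, b$n_regions) / (a$n_regions + b$n_regions)
    )
    tests[[cls]] <- tibble::tibble(
      contrast = paste0(cls, "_vs_CONTROL"),
      statistic = unname(ct$statistic), p_value = ct$p.value
    )
  }
  list(per_class = per_class, tests = dplyr::bind_rows(tests))
}

#' Per-cell CNV counts against a Poisson null
#'
#' Under uniform CNV accrual every cell would carry Poisson-distributed CNV
#' counts with rate `lambda = n_calls / n_cells`. Reports the observed
#' per-cell histogram, the scaled Poisson expectation, and a chi-square
#' goodness-of-fit test with upper-tail classes pooled until each expected
#' count is at least 5.
#'
#' @param final_calls Final call tibble.
#' @param n_cells Number of QC-passing cells.
#' @return List with `histogram` (tibble `k`, `observed`, `expected`),
#'   `lambda`, `statistic`, `df`, `p_value` (`NA` when untestable).
#' @export
cnv_count_poisson <- function(final_calls, n_cells) {
  stopifnot(n_cells >= 1)
  per_cell <- table(final_calls$cell_id)
  counts <- c(as.integer(per_cell),
              rep(0L, n_cells - length(per_cell)))
  lambda <- nrow(final_calls) / n_cells
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  expd <- n_cells * stats::dpois(0:kmax, lambda)
  # final open class absorbs the remaining upper tail mass
  expd[kmax + 1L] <- n_cells * stats::ppois(kmax - 1L, lambda,
                                            lower.tail = FALSE)
  hist <- tibble::tibble(k = 0:kmax, observed = obs, expected = expd)
  if (lambda == 0 || kmax == 0) {
    return(list(histogram = hist, lambda = lambda, statistic = NA_real_,
                df = NA_real_, p_value = NA_real_))
  }
  # pool upper-tail classes until every expected count >= 5
  o <- obs; e <- expd
  while (length(e) > 2 && e[length(e)] < 5) {
    n <- length(e)
    e[n - 1] <- e[n - 1] + e[n]; o[n - 1] <- o[n - 1] + o[n]
    e <- e[-n]; o <- o[-n]
  }
  stat <- sum((o - e)^2 / e)
  # one df for lambda; when pooling leaves only two classes keep df = 1
  df <- max(length(e) - 2, 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(histogram = hist, lambda = lambda, statistic = stat, df = df,
       p_value = p)
}

#' Karyotype matrix: fraction of each autosome deleted per cell
#'
#' For every cell, computes the fraction of each chromosome's base pairs
#' covered by final deletions (overlaps within a cell are unioned first).
#' Cells are ranked by total affected genome fraction; cells above
#' `complex_frac` are flagged as complex karyotypes. A whole-chromosome
#' deletion (monosomy) gives that chromosome fraction 1.
#'
#' @param final_calls Final deletion calls (`cell_id`, `chrom`, `start`,
#'   `end`).
#' @param layout A [genome_layout()].
#' @param cells Optional vector of all cell ids (cells without calls get
#'   all-zero rows).
#' @param complex_frac Genome fraction above which a karyotype is complex
#'   (default 0.05).
#' @return A `karyotype_matrix`: tibble with `cell_id`, one column per
#'   chromosome (fractions in `[0, 1]`), `genome_fraction`, `complex`,
#'   sorted by decreasing `genome_fraction` (ties broken by `cell_id`).
#' @export
karyotype_metrics <- function(final_calls, layout, cells = NULL,
                              complex_frac = 0.05) {
  chroms <- layout$chromosomes
  if (is.null(cells)) cells <- sort(unique(final_calls$cell_id))
  dels <- if ("type" %in% names(final_calls)) {
    final_calls[final_calls$type %in% c("HET_DEL", "HOM_DEL",
                                        "MONOSOMY"), ]
  } else {
    final_calls
  }
  u <- dels |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ merge_intervals(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(bp = .data$end - .data$start) |>
    dplyr::group_by(.data$cell_id, .data$chrom) |>
    dplyr::summarise(bp = sum(.data$bp), .groups = "drop")
  m <- matrix(0, length(cells), nrow(chroms),
              dimnames = list(cells, chroms$chrom))
  if (nrow(u) > 0) {
    m[cbind(match(u$cell_id, cells), match(u$chrom, chroms$chrom))] <- u$bp
  }
  m <- sweep(m, 2, chroms$length, "/")
  gf <- (m %*% chroms$length) / sum(chroms$length)
  out <- tibble::as_tibble(m) |>
    dplyr::mutate(cell_id = cells, .before = 1) |>
    dplyr::mutate(genome_fraction = as.numeric(gf),
                  complex = .data$genome_fraction > complex_frac) |>
    dplyr::arrange(dplyr::desc(.data$genome_fraction), .data$cell_id)
  structure(out, class = c("karyotype_matrix", class(out)))
}

#' Hierarchically cluster karyotypes
#'
#' Agglomerative clustering of cells with each autosome's deleted fraction
#' as an independent dimension. Row order (tie-break) is deterministic by
#' `cell_id`.
#'
#' @param km A `karyotype_matrix` from [karyotype_metrics()].
#' @param k Number of flat clusters to cut (default 2; `NULL` for none).
#' @param method Linkage (default `"average"`).
#' @param metric Distance (default `"euclidean"`).
#' @return List with `hclust` (the dendrogram) and `clusters` (named
#'   integer vector, when `k` given).
#' @export
cluster_karyotypes <- function(km, k = 2, method = "average",
                               metric = "euclidean") {
  chrom_cols <- setdiff(names(km), c("cell_id", "genome_fraction",
                                     "complex"))
  ord <- order(km$cell_id)
  m <- as.matrix(km[ord, chrom_cols])
  rownames(m) <- km$cell_id[ord]
  hc <- stats::hclust(stats::dist(m, method = metric), method = method)
  list(hclust = hc,
       clusters = if (!is.null(k)) stats::cutree(hc, k = k) else NULL)
}
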