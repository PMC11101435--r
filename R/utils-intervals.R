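# Interval helpers (0-based half-open throughout).

#' Merge overlapping or adjacent intervals
#'
#' Union semantics (as `bedtools merge`): intervals that overlap or touch
#' are coalesced per chromosome.
#'
#' @param x Tibble with `chrom`, `start`, `end`.
#' @return Tibble of disjoint merged intervals, sorted.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(tibble::as_tibble(x[, c("chrom", "start", "end")]))
  x |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(grp = cumsum(
      c(TRUE, .data$start[-1] > cummax(.data$end)[-dplyr::n()])
    )) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end")
}

# total bp of (chrom, start, end) covered by interval set `b` (assumed or
# made disjoint)
interval_overlap_bp <- function(chrom, start, end, b) {
  bb <- b[b$chrom == chrom & b$start < end & b$end > start, ]
  if (nrow(bb) == 0) return(0)
  sum(pmin(bb$end, end) - pmax(bb$start, start))
}

# count of features overlapping each region (feature counted once per region)
count_overlaps <- function(regions, features) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(features$chrom == regions$chrom[i] &
          features$start < regions$end[i] &
          features$end > regions$start[i])
  }, numeric(1))
}
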