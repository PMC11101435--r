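#' Construct a genome layout
#'
#' A genome layout is the coordinate backbone of the pipeline: an ordered set
#' of chromosomes with their lengths, plus the uniquely mappable intervals of
#' each chromosome. All coordinates are 0-based, half-open.
#'
#' @param chromosomes A data frame with columns `chrom` (character) and
#'   `length` (bp), one row per chromosome, in the order analyses should use.
#' @param mappable Optional data frame with columns `chrom`, `start`, `end`
#'   giving the uniquely mappable intervals (0-based half-open, disjoint).
#'   When `NULL` every chromosome is treated as fully mappable, which is the
#'   right behaviour for synthetic genomes.
#'
#' @return An object of class `genome_layout`: a list with elements
#'   `chromosomes` (tibble) and `mappable` (tibble).
#' @examples
#' gl <- genome_layout(tibble::tibble(chrom = "chrA", length = 2e6))
#' gl
#' @export
genome_layout <- function(chromosomes, mappable = NULL) {
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (any(chromosomes$length <= 0)) {
    stop("all chromosome lengths must be > 0")
  }
  if (anyDuplicated(chromosomes$chrom)) {
    stop("duplicated chromosome names in layout")
  }
  if (is.null(mappable)) {
    mappable <- tibble::tibble(
      chrom = chromosomes$chrom, start = 0, end = chromosomes$length
    )
  }
  mappable <- tibble::as_tibble(mappable)
  stopifnot(all(c("chrom", "start", "end") %in% names(mappable)))
  mappable <- dplyr::arrange(
    mappable,
    match(.data$chrom, chromosomes$chrom), .data$start
  )
  mappable <- dplyr::semi_join(mappable, chromosomes, by = "chrom")
  # validate: within bounds, sorted, disjoint
  chk <- dplyr::left_join(mappable, chromosomes, by = "chrom")
  if (any(chk$start < 0) || any(chk$end > chk$length) || any(chk$start >= chk$end)) {
    stop("mappable intervals must satisfy 0 <= start < end <= chromosome length")
  }
  ov <- mappable |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]))
  if (any(ov$bad)) stop("mappable intervals overlap; provide disjoint intervals")
  structure(
    list(chromosomes = chromosomes, mappable = mappable),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(
    "<genome_layout> ", nrow(x$chromosomes), " chromosome(s), ",
    format(sum(x$chromosomes$length), big.mark = ","), " bp total, ",
    format(sum(x$mappable$end - x$mappable$start), big.mark = ","),
    " bp mappable\n",
    sep = ""
  )
  invisible(x)
}

#' hg19 autosome lengths
#'
#' Chromosome lengths of the 22 human autosomes (GRCh37/hg19), shipped as
#' built-in constants so that genome-level bookkeeping (for example the 5 Mb
#' partition used by the hotspot analysis) needs no download. Sex chromosomes
#' are deliberately absent: the pipeline restricts itself to autosomes to
#' avoid false monosomy calls on male allosomes.
#'
#' @return A `genome_layout` with 22 fully mappable autosomes (attach a real
#'   mappability track with [genome_layout()] if you have one).
#' @examples
#' nrow(partition_5mb(hg19_autosomes()))
#' @export
hg19_autosomes <- function() {
  lens <- c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566
  )
  genome_layout(tibble::tibble(chrom = names(lens), length = unname(lens)))
}

#' Build variable-width bins of fixed mappable content
#'
#' Tiles each chromosome with bins that each contain exactly
#' `target_mappable` base pairs of uniquely mappable sequence. Bin widths
#' therefore vary: a bin spanning an unmappable gap grows until it has
#' accumulated its mappable quota (the gap is assigned to the bin being
#' accumulated, i.e. to the left bin). A trailing bin holding less than the
#' target is dropped, and the dropped mappable base pairs are reported in the
#' `dropped_bp` attribute.
#'
#' @param layout A [genome_layout()].
#' @param target_mappable Mappable bp per bin (default 500 kb).
#'
#' @return A tibble with columns `bin` (1-based index, global), `chrom`,
#'   `start`, `end` (bp, 0-based half-open), `mappable_bp`. Attribute
#'   `dropped_bp` records mappable bp discarded in sub-target tails.
#' @examples
#' gl <- genome_layout(tibble::tibble(chrom = "chrA", length = 2e6))
#' make_variable_bins(gl, 5e5)
#' @export
make_variable_bins <- function(layout, target_mappable = 5e5) {
  stopifnot(inherits(layout, "genome_layout"), target_mappable > 0)
  dropped <- 0
  out <- vector("list", nrow(layout$chromosomes))
  for (ci in seq_len(nrow(layout$chromosomes))) {
    chrom <- layout$chromosomes$chrom[ci]
    iv <- dplyr::filter(layout$mappable, .data$chrom == !!chrom)
    if (nrow(iv) == 0 || sum(iv$end - iv$start) == 0) {
      warning("chromosome ", chrom, " has no mappable sequence; no bins made")
      next
    }
    # cumulative mappable bp before each interval
    w <- iv$end - iv$start
    cum <- cumsum(w)
    total <- cum[length(cum)]
    nb <- floor(total / target_mappable)
    dropped <- dropped + (total - nb * target_mappable)
    if (nb == 0) next
    # bin k ends where cumulative mappable reaches k * target
    targets <- seq_len(nb) * target_mappable
    idx <- findInterval(targets, cum, left.open = TRUE) + 1L
    # genomic coordinate where cumulative mappable == t inside interval idx
    prev_cum <- c(0, cum)[idx]
    ends <- iv$start[idx] + (targets - prev_cum)
    starts <- c(iv$start[1], ends[-nb])
    out[[ci]] <- tibble::tibble(
      chrom = chrom, start = starts, end = ends,
      mappable_bp = target_mappable
    )
  }
  bins <- dplyr::bind_rows(out)
  if (nrow(bins) > 0) bins <- dplyr::mutate(bins, bin = dplyr::row_number(),
                                            .before = 1)
  attr(bins, "dropped_bp") <- dropped
  bins
}

#' Partition autosomes into contiguous 5 Mb regions
#'
#' Each chromosome is tiled from position 0 with non-overlapping regions of
#' exactly `region_size` bp; the sub-size tail of each chromosome is not
#' considered. On the hg19 autosomes this yields 567 regions.
#'
#' @param layout A [genome_layout()].
#' @param region_size Region width in bp (default 5 Mb).
#' @return A tibble with columns `region` (1-based global index), `chrom`,
#'   `start`, `end`.
#' @examples
#' partition_5mb(genome_layout(tibble::tibble(chrom = "c1", length = 12e6)))
#' @export
partition_5mb <- function(layout, region_size = 5e6) {
  stopifnot(inherits(layout, "genome_layout"), region_size > 0)
  ch <- layout$chromosomes
  n <- floor(ch$length / region_size)
  idx <- rep.int(seq_len(nrow(ch)), n)
  k <- sequence(n)
  tibble::tibble(
    region = seq_along(idx), chrom = ch$chrom[idx],
    start = (k - 1) * region_size, end = k * region_size
  )
}

#' Format a count as a printed percentage
#'
#' Small reporting helper used throughout summaries: `pct(226, 2097)` is
#' `10.8`, the conventional one-decimal percentage.
#'
#' @param n Numerator count.
#' @param d Denominator count.
#' @param digits Decimal digits (default 1).
#' @return Numeric percentage rounded to `digits`.
#' @export
pct <- function(n, d, digits = 1) round(100 * n / d, digits)
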