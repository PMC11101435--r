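# ggplot2 displays for the main result types.

#' Plot one cell's copy-number profile
#'
#' Bins along the genome with their copy-number estimates; optional
#' segment means and call shading.
#'
#' @param cn Copy-number matrix (cells x bins).
#' @param bins Bin table.
#' @param cell_id Which cell to draw.
#' @param segments Optional segment tibble from [segment_cells()].
#' @param calls Optional call tibble to shade.
#' @return A ggplot object.
#' @export
plot_cell_profile <- function(cn, bins, cell_id, segments = NULL,
                              calls = NULL) {
  df <- dplyr::mutate(bins, cn = cn[cell_id, ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                        y = .data$cn)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::geom_hline(yintercept = 2, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "position (bp)", y = "copy number",
                  title = cell_id) +
    ggplot2::theme_minimal()
  if (!is.null(calls)) {
    cc <- calls[calls$cell_id == cell_id, ]
    if (nrow(cc) > 0) {
      p <- p + ggplot2::geom_rect(
        data = cc, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf, fill = .data$type),
        alpha = 0.15
      )
    }
  }
  if (!is.null(segments)) {
    ss <- segments[segments$cell_id == cell_id, ]
    p <- p + ggplot2::geom_segment(
      data = ss, inherit.aes = FALSE, colour = "red",
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$median_cn, yend = .data$median_cn)
    )
  }
  p
}

#' @export
autoplot.scoval_calibration <- function(object, ...) {
  grid <- seq(max(0, min(object$means) - 1), max(object$means) + 1,
              length.out = 400)
  dens <- purrr::map_dfr(seq_along(object$means), function(j) {
    tibble::tibble(
      cn = grid, component = factor(object$components[j]),
      density = object$weights[j] *
        stats::dnorm(grid, object$means[j], object$sds[j])
    )
  })
  ggplot2::ggplot(dens, ggplot2::aes(.data$cn, .data$density,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(object$del_cutoff,
                                       object$dup_cutoff),
                        linetype = 2) +
    ggplot2::labs(x = "segment median copy number",
                  y = "weighted density",
                  title = "copy-number state calibration") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.karyotype_matrix <- function(object, ...) {
  chrom_cols <- setdiff(names(object),
                        c("cell_id", "genome_fraction", "complex"))
  long <- tidyr::pivot_longer(object, dplyr::all_of(chrom_cols),
                              names_to = "chrom", values_to = "fraction")
  long$cell_id <- factor(long$cell_id, levels = rev(object$cell_id))
  long$chrom <- factor(long$chrom, levels = chrom_cols)
  ggplot2::ggplot(long, ggplot2::aes(.data$chrom, .data$cell_id,
                                     fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colours = c("steelblue", "gold", "orange", "red"),
      limits = c(0, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "deleted\nfraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot region-level permutation significance along the genome
#'
#' @param region_stats Tibble from [region_pvalues()].
#' @return A ggplot object.
#' @export
plot_region_significance <- function(region_stats) {
  ggplot2::ggplot(region_stats,
                  ggplot2::aes((.data$start + .data$end) / 2,
                               1 - .data$p_value, colour = .data$klass)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(
      HOT = "red", COLD = "blue", CONTROL = "grey60",
      COLD_REMOVED = "lightblue"
    )) +
    ggplot2::labs(x = "position (bp)", y = "regional significance (1 - p)") +
    ggplot2::theme_minimal()
}

#' Plot the per-cell CNV-count histogram against the Poisson expectation
#'
#' @param poisson_fit Result of [cnv_count_poisson()].
#' @return A ggplot object.
#' @export
plot_cnv_count <- function(poisson_fit) {
  h <- poisson_fit$histogram
  ggplot2::ggplot(h, ggplot2::aes(.data$k, .data$observed)) +
    ggplot2::geom_col(fill = "purple", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "blue",
                       linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "CNVs per cell", y = "cells (log scale)",
                  subtitle = sprintf("Poisson lambda = %.3g, GOF p = %.3g",
                                     poisson_fit$lambda,
                                     poisson_fit$p_value)) +
    ggplot2::theme_minimal()
}
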