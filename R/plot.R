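# Rainfall plots: IMD against genomically ordered variant index, with
# kataegis loci shaded and an optional segmentation overlay.

substitution_palette <- c(
  "C>A" = "#2EBAED", "C>G" = "#000000", "C>T" = "#DE1C14",
  "T>A" = "#D4D2D2", "T>C" = "#ADCC54", "T>G" = "#F0D0CE",
  "MNV" = "#8E44AD", "indel" = "#E67E22", "other" = "#7F8C8D"
)

#' Rainfall plot of a kataegis detection result
#'
#' Plots every variant's intermutation distance (log10 scale, floored at
#' 1 bp) against its genomic ordinal, coloured by substitution class.
#' Called kataegis loci are shaded rectangles with their member variants
#' emphasised; with `show_segmentation`, detected changepoints appear as
#' vertical lines and each segment's mean IMD as a horizontal line.
#'
#' @param result A `katdetect` from [detect_kataegis()].
#' @param chromosomes Chromosome selection, or `"all"` (default). With
#'   several chromosomes the boundaries are marked.
#' @param show_segmentation Overlay changepoints and per-segment mean IMDs.
#' @param point_size Point size for unflagged variants.
#' @return A `ggplot` object.
#' @export
rainfall_plot <- function(result, chromosomes = "all",
                          show_segmentation = FALSE, point_size = 0.8) {
  stopifnot(inherits(result, "katdetect"))
  v <- result$variants
  if (!identical(chromosomes, "all")) {
    keep <- v$chromosome %in% chromosomes
    if (!any(keep)) {
      abort(sprintf("No variants on selected chromosome(s); available: %s",
                    paste(unique(v$chromosome), collapse = ", ")))
    }
    v <- v[keep, ]
  }
  chrom_order <- unique(v$chromosome)
  v <- v[order(match(v$chromosome, chrom_order), v$start), ]
  v$ordinal <- seq_len(nrow(v))
  v$class <- factor(classify_substitution(v$ref, v$alt),
                    levels = names(substitution_palette))
  v$imd_plot <- pmax(v$imd, 1)

  loci <- result$loci[result$loci$chromosome %in% chrom_order, , drop = FALSE]
  rects <- NULL
  if (nrow(loci) > 0) {
    rects <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
      inside <- v$chromosome == loci$chromosome[i] &
        v$start >= loci$genomic_start[i] & v$start <= loci$genomic_end[i]
      tibble(xmin = min(v$ordinal[inside]) - 0.5,
             xmax = max(v$ordinal[inside]) + 0.5)
    })
  }

  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$ordinal,
                                       y = .data$imd_plot))
  if (!is.null(rects)) {
    p <- p + ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, fill = "#AED6F1", alpha = 0.5,
      inherit.aes = FALSE
    )
  }
  if (isTRUE(show_segmentation)) {
    offsets <- c(0, cumsum(table(factor(v$chromosome,
                                        levels = chrom_order))))
    seg <- result$segments[result$segments$chromosome %in% chrom_order, ,
                           drop = FALSE]
    seg$offset <- offsets[match(seg$chromosome, chrom_order)]
    k_per <- table(factor(v$chromosome, levels = chrom_order))
    seg$k <- as.integer(k_per[match(seg$chromosome, chrom_order)])
    seg$x_from <- seg$offset + pmin(seg$first_index, seg$k) - 0.5
    seg$x_to <- seg$offset + pmin(seg$last_index, seg$k) + 0.5
    cuts <- seg[seg$last_index < seg$k, , drop = FALSE]
    if (nrow(cuts) > 0) {
      p <- p + ggplot2::geom_vline(
        data = cuts, ggplot2::aes(xintercept = .data$x_to),
        linetype = "dashed", colour = "grey40"
      )
    }
    seg_means <- seg[!is.na(seg$mean_imd), , drop = FALSE]
    p <- p + ggplot2::geom_segment(
      data = seg_means,
      ggplot2::aes(x = .data$x_from, xend = .data$x_to,
                   y = pmax(.data$mean_imd, 1),
                   yend = pmax(.data$mean_imd, 1)),
      colour = "black", linewidth = 0.6, inherit.aes = FALSE
    )
  }
  p <- p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class),
                        size = point_size) +
    ggplot2::geom_point(
      data = v[v$in_kataegis, , drop = FALSE],
      ggplot2::aes(colour = .data$class), size = point_size * 2
    ) +
    ggplot2::scale_colour_manual(values = substitution_palette,
                                 drop = FALSE, name = "Substitution") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Variant (ordered by genomic location)",
                  y = "Intermutation distance (bp)")
  if (length(chrom_order) > 1) {
    bounds <- cumsum(table(factor(v$chromosome, levels = chrom_order)))
    p <- p + ggplot2::geom_vline(xintercept = head(bounds, -1) + 0.5,
                                 colour = "grey80")
  }
  p
}

#' @rdname rainfall_plot
#' @param object A `katdetect` object.
#' @param ... Passed on to [rainfall_plot()].
#' @method autoplot katdetect
#' @export
autoplot.katdetect <- function(object, ...) {
  rainfall_plot(object, ...)
}
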