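#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot local-PCA MDS scores along a contig
#'
#' Window MDS1 against window midpoint; candidate regions (if supplied)
#' are shaded. Inversions appear as runs of outlier windows.
#'
#' @param object a [local_pca()] result.
#' @param regions optional region tibble to shade.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot local_pca
#' @export
autoplot.local_pca <- function(object, regions = NULL, ...) {
  w <- object$windows
  w$mid <- (w$start + w$end) / 2
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$mid / 1e6,
                                       y = .data$mds1)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = mean(w$mds1) +
                          c(-2, 2) * stats::sd(w$mds1),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = sprintf("%s position (Mb)", object$contig),
                  y = "MDS1") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
      inherit.aes = FALSE)
  }
  p
}

#' Karyotype genotyping diagnostic plot
#'
#' Region PC1 against per-sample heterozygosity, coloured by assigned
#' karyotype: three clusters with an elevated-heterozygosity middle group
#' are the signature of a genotypable inversion.
#'
#' @param kt an `inv_karyotype` from [genotype_inversion()].
#' @return a ggplot.
#' @export
plot_karyotype <- function(kt) {
  ggplot2::ggplot(tibble::as_tibble(kt),
                  ggplot2::aes(x = .data$pc1, y = .data$het,
                               colour = .data$genotype)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "region PC1", y = "region heterozygosity",
                  colour = "karyotype") +
    ggplot2::theme_minimal()
}

#' Windowed statistic along contigs
#'
#' @param ws output of [window_stats()].
#' @param stat column to draw (for example `"fst"`, `"pi"`, `"tajd"`).
#' @return a ggplot faceted by contig.
#' @export
plot_windows <- function(ws, stat = "fst") {
  ws$mid <- (ws$start + ws$end) / 2
  ggplot2::ggplot(ws, ggplot2::aes(x = .data$mid / 1e6,
                                   y = .data[[stat]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = stat) +
    ggplot2::theme_minimal()
}

#' Mutation-load distribution by group
#'
#' Boxplots of per-window piN/piS per group (collinear background vs
#' inversion haplotype classes).
#'
#' @param load_tbl row-bound [pin_pis_windows()] output.
#' @return a ggplot.
#' @export
plot_load <- function(load_tbl) {
  ggplot2::ggplot(load_tbl, ggplot2::aes(x = .data$group,
                                         y = .data$ratio)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = expression(pi[N] / pi[S])) +
    ggplot2::theme_minimal()
}
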