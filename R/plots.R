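#' Manhattan plot of a GWA scan
#'
#' Plots `-log10(q)` against absolute genomic position, chromosomes
#' alternating in shade, with the significance threshold drawn at the FDR
#' cutoff and peak SNPs highlighted if peaks are supplied.
#'
#' @param associations Tibble from [gwa_scan()] (one miRNA, or facetted by
#'   miRNA when several are present).
#' @param peaks Optional peak tibble from [call_peaks()].
#' @param fdr Threshold line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(associations, peaks = NULL, fdr = 0.05) {
  df <- dplyr::arrange(associations, .data$chrom, .data$pos)
  offsets <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  df <- dplyr::left_join(df, offsets, by = "chrom") |>
    dplyr::mutate(abs_pos = (.data$pos + .data$offset) / 1e6,
                  shade = factor(.data$chrom %% 2))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_pos,
                                        y = -log10(.data$q),
                                        colour = .data$shade)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(fdr), colour = "red",
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("steelblue4", "steelblue2")) +
    ggplot2::labs(x = "absolute SNP position (Mb)",
                  y = expression(-log[10](q))) +
    ggplot2::theme_minimal()
  if (length(unique(df$mirna)) > 1) {
    p <- p + ggplot2::facet_wrap(~mirna)
  }
  if (!is.null(peaks) && nrow(peaks) > 0) {
    pk <- dplyr::left_join(peaks, offsets, by = "chrom") |>
      dplyr::mutate(abs_pos = (.data$peak_pos + .data$offset) / 1e6)
    p <- p + ggplot2::geom_point(
      data = pk, ggplot2::aes(x = .data$abs_pos, y = -log10(.data$peak_q)),
      colour = "orange", size = 2, inherit.aes = FALSE)
  }
  p
}

#' Mean-variance trend of a voom-normalized expression set
#'
#' Square-root residual standard deviation against average log2 count per
#' miRNA, the relationship the precision weights are interpolated from.
#'
#' @param norm A [voom_transform()] result.
#' @return A ggplot object.
#' @export
plot_mean_variance <- function(norm) {
  stopifnot(inherits(norm, "voom_norm"))
  mean_logcpm <- rowMeans(norm$logcpm)
  sqrt_sd <- sqrt(apply(norm$logcpm, 1, sd))
  ggplot2::ggplot(tibble(mean_logcpm = mean_logcpm, sqrt_sd = sqrt_sd),
                  ggplot2::aes(.data$mean_logcpm, .data$sqrt_sd)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "mean log2-CPM", y = "sqrt(standard deviation)") +
    ggplot2::theme_minimal()
}

#' Heritability versus LRT significance
#'
#' Scatter of estimated heritability against `-log10(p)` of its likelihood
#' ratio test across miRNAs, coloured by FDR significance.
#'
#' @param h2_table Output of [test_heritability()].
#' @return A ggplot object.
#' @export
plot_h2 <- function(h2_table) {
  ggplot2::ggplot(h2_table,
                  ggplot2::aes(.data$h2, -log10(.data$p),
                               colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(hat(h)^2), y = expression(-log[10](p)),
                  colour = "FDR < threshold") +
    ggplot2::theme_minimal()
}
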