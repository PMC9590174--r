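#' Plot predicted reversal potency against drug sensitivity
#'
#' Scatter of sRGES vs log10 AC50 per compound with a least-squares trend
#' line; annotated with the Pearson correlation. Mirrors the standard
#' evaluation figure for signature-reversal predictions.
#'
#' @param object A `reversal_correlation` from [correlate_efficacy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reversal_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$srges, y = .data$log10_ac50)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::labs(
      x = "sRGES (lower = stronger predicted reversal)",
      y = expression(log[10] ~ AC[50]),
      title = sprintf("Reversal potency vs sensitivity (r = %.2f, p = %.2g, n = %d)",
                      object$r, object$p, object$n)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.reversal_correlation
#' @param x A `reversal_correlation`.
#' @export
tidy.reversal_correlation <- function(x, ...) {
  tibble(estimate = x$r, p.value = x$p, n = x$n, method = "pearson")
}

#' @rdname autoplot.reversal_correlation
#' @export
glance.reversal_correlation <- function(x, ...) tidy(x)

#' Waterfall plot of summarized reversal scores
#'
#' Compounds ordered by sRGES with the reversal cutoff marked; reversing
#' compounds (below the cutoff) highlighted.
#'
#' @param object An `srges_table`.
#' @param cutoff Reversal cutoff drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srges_table <- function(object, cutoff = -0.1, ...) {
  df <- as_tibble(object) |>
    arrange(.data$srges) |>
    mutate(rank = row_number(), reversing = .data$srges < cutoff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$srges,
                                   fill = .data$reversing)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = "compound rank", y = "sRGES") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param object A `de_table`.
#' @param lfc_min,padj_max Thresholds drawn as reference lines and used to
#'   colour significant genes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_table <- function(object, lfc_min = 1, padj_max = 0.05, ...) {
  df <- as_tibble(object) |>
    mutate(hit = .data$padj < padj_max & abs(.data$log2fc) > lfc_min)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$pvalue, 1e-300)),
                                   colour = .data$hit)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
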