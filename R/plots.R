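#' Plot a filtering funnel
#'
#' Bar chart of variants surviving each cascade stage.
#'
#' @param funnel Funnel tibble `(stage, n_in, n_out)`.
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnel) {
  df <- dplyr::mutate(funnel,
                      stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "variants retained",
                  title = "Variant filtering funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot rdSNV enrichment against gene intolerance
#'
#' Per-gene co-segregating rdSNV counts against the genome-wide RVIS
#' percentile; candidate genes (z > 2 in the most intolerant decile) are
#' highlighted and labelled.
#'
#' @param object An `fs_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fs_enrichment
#' @export
autoplot.fs_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  z2_count <- min(df$rdsnv_count[df$zscore > 2], Inf)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rvis_percentile,
                                        y = .data$rdsnv_count)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$candidate),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "RVIS percentile (low = intolerant)",
                  y = "co-segregating rdSNVs",
                  title = "rdSNV enrichment vs. gene intolerance") +
    ggplot2::theme_minimal()
  if (is.finite(z2_count)) {
    p <- p + ggplot2::geom_hline(yintercept = z2_count - 0.5,
                                 colour = "red", linetype = "dashed")
  }
  cand <- df[df$candidate, ]
  if (nrow(cand)) {
    p <- p + ggplot2::geom_text(data = cand,
                                ggplot2::aes(label = .data$gene),
                                vjust = -0.6, size = 2.6, colour = "red")
  }
  p
}

#' Plot normalized enrichment scores of a GSEA result
#'
#' @param object An `fs_gsea` object.
#' @param fdr Significance threshold used for the fill.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fs_gsea
#' @export
autoplot.fs_gsea <- function(object, fdr = 0.05, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(significant = .data$fdr_q < fdr,
                  set = stats::reorder(.data$set, .data$nes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$set,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = sprintf("FDR q < %.2g", fdr)) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL,
                  title = "Preranked GSEA") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot per-group CADD score distributions
#'
#' @param object An `fs_pathogenicity` object.
#' @param threshold Horizontal reference line (high-CADD threshold).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fs_pathogenicity
#' @export
autoplot.fs_pathogenicity <- function(object, threshold = 20, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$group, y = .data$cadd_scaled)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "scaled CADD",
                  title = "Variant pathogenicity by carrier group") +
    ggplot2::theme_minimal()
}
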