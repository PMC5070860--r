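#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a GSEA result
#'
#' @param x An `fs_gsea` object.
#' @param ... Unused.
#' @return Tibble with one row per gene set; the leading edge is collapsed
#'   to a comma-separated string.
#' @method tidy fs_gsea
#' @export
tidy.fs_gsea <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(leading_edge = vapply(.data$leading_edge, paste,
                                        character(1), collapse = ","))
}

#' @rdname tidy.fs_gsea
#' @method glance fs_gsea
#' @export
glance.fs_gsea <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_perm = attr(x, "n_perm"),
    weight = attr(x, "weight"),
    n_significant = sum(x$fdr_q < 0.05),
    top_set = x$set[1],
    top_fdr_q = x$fdr_q[1]
  )
}

#' Tidy a burden scan
#'
#' @param x An `fs_burden` object.
#' @param ... Unused.
#' @return The per-gene burden tibble.
#' @method tidy fs_burden
#' @export
tidy.fs_burden <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.fs_burden
#' @method glance fs_burden
#' @export
glance.fs_burden <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    count_per_family = attr(x, "count_per_family"),
    novel_only = if (nrow(x)) x$novel_only[1] else NA,
    min_p = if (nrow(x)) min(x$p_one_tailed) else NA_real_,
    top_gene = if (nrow(x)) x$gene[1] else NA_character_
  )
}

#' Tidy an intolerance enrichment result
#'
#' @param x An `fs_enrichment` object.
#' @param ... Unused.
#' @return Per-gene tibble `(gene, rdsnv_count, zscore, rvis_percentile,
#'   rvis_bin, candidate)`.
#' @method tidy fs_enrichment
#' @export
tidy.fs_enrichment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.fs_enrichment
#' @method glance fs_enrichment
#' @export
glance.fs_enrichment <- function(x, ...) {
  eb <- attr(x, "extreme_bin_p")
  tibble::tibble(
    n_genes = nrow(x),
    n_candidates = sum(x$candidate),
    p_intolerant_excess = eb$p_low,
    p_tolerant_excess = eb$p_high
  )
}
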