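#' Per-gene cumulative counts of co-segregating rdSNVs
#'
#' Counts unique variant keys per gene across families (a variant
#' co-segregating in two families is counted once; a compound-het pair
#' contributes its two member variants). Genes of the declared universe
#' with no segregating variant get a zero; segregating variants in genes
#' outside the universe are logged and excluded.
#'
#' @param segvars Segregating-variant tibble from [collect_rdsnvs()].
#' @param gene_universe Character vector of all genes under study.
#' @return Tibble `(gene, rdsnv_count)` covering the full universe.
#' @export
gene_counts <- function(segvars, gene_universe) {
  outside <- setdiff(unique(segvars$gene), gene_universe)
  if (length(outside)) {
    message(sprintf("excluding %d gene(s) outside the declared universe",
                    length(outside)))
  }
  counts <- segvars |>
    dplyr::filter(.data$gene %in% gene_universe) |>
    dplyr::distinct(.data$gene, .data$variant_key) |>
    dplyr::count(.data$gene, name = "rdsnv_count")
  tibble::tibble(gene = gene_universe) |>
    dplyr::left_join(counts, by = "gene") |>
    dplyr::mutate(rdsnv_count = tidyr::replace_na(.data$rdsnv_count, 0L))
}

#' Standardize per-gene counts to z-scores
#'
#' `z = (count - mean) / sd` with the mean and population standard
#' deviation (denominator n) taken over the full gene universe including
#' zero-count genes.
#'
#' @param counts Tibble `(gene, rdsnv_count)` from [gene_counts()].
#' @return Input with an added `zscore` column.
#' @export
gene_zscores <- function(counts) {
  x <- counts$rdsnv_count
  if (length(x) < 2) stop_format("need at least 2 genes to standardize")
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) {
    stop_format("all genes have identical counts; z-scores are undefined")
  }
  dplyr::mutate(counts, zscore = (.data$rdsnv_count - mu) / sd_pop)
}

#' Bin genes into RVIS percentile deciles
#'
#' Bin `b` holds genes with RVIS percentile in `((b-1)*10, b*10]`; bin 1 is
#' the most intolerant decile. Genes without an RVIS percentile are logged
#' and excluded from binning only.
#'
#' @param counts Tibble with `gene` and per-gene values (counts/z-scores).
#' @param rvis Tibble `(gene, rvis_percentile)`.
#' @param n_bins Number of equal-width percentile bins (default 10).
#' @return `counts` joined with `rvis_percentile` and integer `rvis_bin`
#'   (`NA` for genes without a percentile).
#' @export
bin_by_rvis <- function(counts, rvis, n_bins = 10) {
  out <- dplyr::left_join(counts, rvis, by = "gene")
  n_missing <- sum(is.na(out$rvis_percentile))
  if (n_missing) {
    message(sprintf("%d gene(s) without RVIS percentile excluded from binning",
                    n_missing))
  }
  width <- 100 / n_bins
  dplyr::mutate(
    out,
    rvis_bin = as.integer(pmin(ceiling(.data$rvis_percentile / width),
                               n_bins))
  )
}

#' Test for an excess of rdSNVs in the extreme RVIS bins
#'
#' One-sided Wilcoxon rank-sum tests of per-gene rdSNV counts in the most
#' intolerant bin (bin 1) and the most tolerant bin (`n_bins`), each
#' against the pooled counts of all interior bins.
#'
#' @param binned Output of [bin_by_rvis()].
#' @param mode Wilcoxon mode, see [wilcoxon_rank_sum()].
#' @return List with one-sided p-values `p_low` (intolerant-end excess)
#'   and `p_high` (tolerant-end excess); `NA` when a comparison group is
#'   empty.
#' @export
extreme_bin_excess_test <- function(binned, mode = "normal_approx") {
  n_bins <- max(binned$rvis_bin, na.rm = TRUE)
  inner <- binned$rdsnv_count[!is.na(binned$rvis_bin) &
                                binned$rvis_bin %in% 2:(n_bins - 1)]
  one_tail <- function(b) {
    x <- binned$rdsnv_count[!is.na(binned$rvis_bin) & binned$rvis_bin == b]
    if (length(x) == 0 || length(inner) == 0) return(NA_real_)
    wilcoxon_rank_sum(x, inner, mode = mode,
                      alternative = "greater")$p.value
  }
  list(p_low = one_tail(1), p_high = one_tail(n_bins))
}

#' Call candidate genes from enrichment and intolerance
#'
#' Candidates show an excess of co-segregating rdSNVs (z-score strictly
#' above 2) and lie in the most intolerant RVIS decile (percentile <= 10).
#' Ordered by descending z-score (ties by gene symbol).
#'
#' @param enrichment Tibble with `gene`, `zscore`, `rvis_percentile`.
#' @param z_threshold Strict z-score cutoff (default 2).
#' @param intolerant_percentile Maximum RVIS percentile (default 10).
#' @return Tibble of candidate rows, with a logical `candidate` column
#'   added to the attribute-free copy of the input available via
#'   `attr(, "all")`.
#' @export
call_candidates <- function(enrichment, z_threshold = 2,
                            intolerant_percentile = 10) {
  all_genes <- dplyr::mutate(
    enrichment,
    candidate = .data$zscore > z_threshold &
      !is.na(.data$rvis_percentile) &
      .data$rvis_percentile <= intolerant_percentile
  )
  cands <- all_genes |>
    dplyr::filter(.data$candidate) |>
    dplyr::arrange(dplyr::desc(.data$zscore), .data$gene)
  structure(cands, all = all_genes)
}

#' Gene-intolerance enrichment analysis of co-segregating rdSNVs
#'
#' End-to-end wrapper: per-gene unique rdSNV counts over the universe,
#' z-score transformation, RVIS decile binning, extreme-bin excess tests
#' and candidate calling.
#'
#' @param segvars Segregating-variant tibble from [collect_rdsnvs()].
#' @param rvis Tibble `(gene, rvis_percentile)`.
#' @param gene_universe All genes under study.
#' @param n_bins Number of RVIS bins.
#' @return Object of class `fs_enrichment`: a tibble `(gene, rdsnv_count,
#'   zscore, rvis_percentile, rvis_bin, candidate)` with attributes
#'   `extreme_bin_p` (list `p_low`, `p_high`) and `candidates` (the
#'   ordered candidate subset).
#' @export
rvis_enrichment <- function(segvars, rvis, gene_universe, n_bins = 10) {
  enr <- gene_counts(segvars, gene_universe) |>
    gene_zscores() |>
    bin_by_rvis(rvis, n_bins = n_bins)
  cands <- call_candidates(enr)
  all_genes <- attr(cands, "all")
  attr(cands, "all") <- NULL
  structure(
    all_genes,
    extreme_bin_p = extreme_bin_excess_test(enr),
    candidates = cands,
    class = c("fs_enrichment", class(all_genes))
  )
}

#' Candidate genes of an enrichment analysis
#'
#' @param x An `fs_enrichment` object.
#' @return Tibble of candidate genes ordered by descending z-score.
#' @export
candidates <- function(x) {
  attr(x, "candidates")
}
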