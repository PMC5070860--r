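as_score_groups <- function(scores_by_group) {
  if (is.data.frame(scores_by_group)) {
    split(scores_by_group[[2]], scores_by_group[[1]])
  } else {
    scores_by_group
  }
}

#' Pairwise CADD score comparisons between carrier groups
#'
#' Two-sided Wilcoxon rank-sum tests of per-variant scaled CADD scores for
#' every pair of groups (typically cases, unaffected relatives, controls).
#' Each variant contributes once per group. Pairs where either group has
#' fewer than 2 scores are not evaluable (`NA` p).
#'
#' @param scores_by_group Named list of numeric score vectors, or a
#'   two-column data frame `(group, score)`.
#' @param mode Wilcoxon mode, see [wilcoxon_rank_sum()].
#' @return Tibble `(group1, group2, n1, n2, median1, median2, p_wilcoxon)`.
#' @export
cadd_group_compare <- function(scores_by_group, mode = "normal_approx") {
  groups <- as_score_groups(scores_by_group)
  if (any(lengths(groups) == 0)) stop_format("each group must be non-empty")
  pairs <- utils::combn(names(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    x <- groups[[g1]]
    y <- groups[[g2]]
    p <- if (length(x) < 2 || length(y) < 2) NA_real_ else {
      wilcoxon_rank_sum(x, y, mode = mode)$p.value
    }
    tibble::tibble(group1 = g1, group2 = g2, n1 = length(x),
                   n2 = length(y), median1 = stats::median(x),
                   median2 = stats::median(y), p_wilcoxon = p)
  })
}

#' Test group differences in the fraction of high-CADD variants
#'
#' For each group the fraction of variants with scaled CADD strictly above
#' the threshold (a score exactly at the threshold does not exceed it),
#' then a 2x2 chi-square test (exceeds vs not, by group) for every group
#' pair. Degenerate pairs where every variant falls on the same side of
#' the threshold have statistic 0 and p = 1; a group with no variants is
#' not evaluable.
#'
#' @param scores_by_group Named list of score vectors or two-column data
#'   frame.
#' @param threshold Strict scaled CADD threshold (default 20).
#' @return List with `fractions` (named per-group fractions) and `tests`
#'   (tibble `group1`, `group2`, `statistic`, `p_chisq`).
#' @export
high_cadd_fraction_test <- function(scores_by_group, threshold = 20) {
  if (threshold <= 0) stop_format("threshold must be positive")
  groups <- as_score_groups(scores_by_group)
  fractions <- vapply(groups, function(s) {
    if (length(s) == 0) NA_real_ else mean(s > threshold)
  }, numeric(1))
  pairs <- utils::combn(names(groups), 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    x <- groups[[g1]]
    y <- groups[[g2]]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble::tibble(group1 = g1, group2 = g2,
                            statistic = NA_real_, p_chisq = NA_real_))
    }
    a <- sum(x > threshold)
    b <- sum(x <= threshold)
    c_ <- sum(y > threshold)
    d <- sum(y <= threshold)
    if (a + c_ == 0 || b + d == 0) {
      return(tibble::tibble(group1 = g1, group2 = g2, statistic = 0,
                            p_chisq = 1))
    }
    cs <- chi_square_2x2(a, b, c_, d)
    tibble::tibble(group1 = g1, group2 = g2, statistic = cs$statistic,
                   p_chisq = cs$p.value)
  })
  list(fractions = fractions, tests = tests)
}

#' Per-gene-set CADD enrichment between cases and controls
#'
#' For each gene set, compares the scaled CADD scores of case variants in
#' member genes against control variants in member genes (Wilcoxon
#' rank-sum, two-sided) with Benjamini-Hochberg correction across sets.
#' Sets with fewer than 2 variants in either group are skipped.
#'
#' @param case_variants,control_variants Tibbles with columns `gene` and
#'   `cadd_scaled` (one row per variant in the group).
#' @param sets Named list of gene sets.
#' @return Tibble `(set, n_case, n_control, median_case, median_control,
#'   p_wilcoxon, fdr_q)` for tested sets, sorted by q then p.
#' @export
per_set_cadd_enrichment <- function(case_variants, control_variants, sets) {
  rows <- purrr::imap(sets, function(members, nm) {
    x <- case_variants$cadd_scaled[case_variants$gene %in% members]
    y <- control_variants$cadd_scaled[control_variants$gene %in% members]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    tibble::tibble(
      set = nm, n_case = length(x), n_control = length(y),
      median_case = stats::median(x), median_control = stats::median(y),
      p_wilcoxon = wilcoxon_rank_sum(x, y)$p.value
    )
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) return(res)
  res$fdr_q <- bh_fdr(res$p_wilcoxon)
  dplyr::arrange(res, .data$fdr_q, .data$p_wilcoxon, .data$set)
}

#' CADD pathogenicity report for a cohort
#'
#' Assembles the per-group variant score sets — cases: unique
#' co-segregating rdSNVs; unaffected relatives: filtered variants carried
#' by at least one unaffected family member; controls: filtered variants
#' carried by at least one population control — and runs the pairwise
#' Wilcoxon comparisons, the high-CADD fraction chi-square tests and the
#' per-set CADD enrichment.
#'
#' @param cohort An `fs_cohort`.
#' @param filtered Filtered annotation tibble from [filter_variants()].
#' @param segvars Segregating-variant tibble from [collect_rdsnvs()].
#' @param threshold High-CADD threshold (strict, default 20).
#' @return Object of class `fs_pathogenicity`: list with `scores` (tibble
#'   `group`, `variant_key`, `gene`, `cadd_scaled`), `group_compare`,
#'   `high_cadd` and `per_set` components.
#' @export
cadd_pathogenicity <- function(cohort, filtered, segvars, threshold = 20) {
  ped <- cohort$pedigree
  g <- cohort$variant_table$genotypes
  keys <- intersect(filtered$variant_key, rownames(g))
  ann <- filtered[match(keys, filtered$variant_key), ]

  carried_by <- function(ids) {
    if (length(ids) == 0 || length(keys) == 0) return(character(0))
    sub <- g[keys, ids, drop = FALSE]
    keys[rowSums(sub >= 1, na.rm = TRUE) > 0]
  }
  unaff_ids <- ped$individual_id[ped$role == "family_member" &
                                   ped$status == "unaffected"]
  ctrl_ids <- ped$individual_id[ped$role == "population_control"]

  case_keys <- unique(segvars$variant_key)
  group_tbl <- function(group, ks) {
    idx <- match(ks, ann$variant_key)
    tibble::tibble(group = group, variant_key = ks,
                   gene = ann$gene[idx], cadd_scaled = ann$cadd_scaled[idx])
  }
  scores <- dplyr::bind_rows(
    group_tbl("cases", intersect(case_keys, keys)),
    group_tbl("unaffected_relatives", carried_by(unaff_ids)),
    group_tbl("controls", carried_by(ctrl_ids))
  )
  by_group <- split(scores$cadd_scaled, scores$group)
  structure(
    list(
      scores = scores,
      group_compare = cadd_group_compare(by_group),
      high_cadd = high_cadd_fraction_test(by_group, threshold = threshold),
      per_set = per_set_cadd_enrichment(
        scores[scores$group == "cases", c("gene", "cadd_scaled")],
        scores[scores$group == "controls", c("gene", "cadd_scaled")],
        cohort$gene_sets
      )
    ),
    class = "fs_pathogenicity"
  )
}

#' @export
print.fs_pathogenicity <- function(x, ...) {
  cat("<fs_pathogenicity>\n  group sizes:\n")
  print(table(x$scores$group))
  cat("  pairwise Wilcoxon:\n")
  print(as.data.frame(x$group_compare))
  invisible(x)
}
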