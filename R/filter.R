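#' Filtering cascade configuration
#'
#' @param maf_threshold Reference-population MAF cutoff; variants with
#'   MAF strictly below it (or absent) are kept. Default 0.001 (0.1%).
#' @param min_damaging_predictors Minimum damaging predictor calls (of 4)
#'   for a missense variant to pass the consensus stage. Loss-of-function
#'   variants are exempt.
#' @param lof_classes Functional classes counted as loss-of-function.
#' @param cadd_rank_floor Scaled CADD floor used by [rank_variants()].
#' @return Object of class `fs_filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.001,
                          min_damaging_predictors = 2,
                          lof_classes = c("stopgain", "frameshift", "splice"),
                          cadd_rank_floor = 15) {
  if (maf_threshold <= 0 || maf_threshold >= 1) {
    stop_format("maf_threshold must lie in (0, 1)")
  }
  if (!min_damaging_predictors %in% 1:4) {
    stop_format("min_damaging_predictors must be in 1..4")
  }
  structure(
    list(maf_threshold = maf_threshold,
         min_damaging_predictors = min_damaging_predictors,
         lof_classes = lof_classes,
         missense_class = "nonsynonymous",
         cadd_rank_floor = cadd_rank_floor),
    class = "fs_filter_config"
  )
}

#' Classify functional annotation classes
#'
#' Maps annotation classes to the three categories the cascade
#' distinguishes: `stopgain`, `frameshift` and `splice` are
#' loss-of-function; `nonsynonymous` is missense; `synonymous` and `other`
#' are other.
#'
#' @param functional_class Character vector of annotation classes.
#' @return Character vector in `{"lof", "missense", "other"}`.
#' @export
classify_functional <- function(functional_class) {
  unknown <- setdiff(functional_class, functional_classes)
  if (length(unknown)) {
    stop_format("unknown functional class: %s", unknown[1])
  }
  dplyr::case_when(
    functional_class %in% c("stopgain", "frameshift", "splice") ~ "lof",
    functional_class == "nonsynonymous" ~ "missense",
    TRUE ~ "other"
  )
}

#' Predictor consensus rule
#'
#' TRUE when at least `min_k` of the four predictor calls are damaging;
#' missing calls count as not damaging (conservative: missingness cannot
#' inflate consensus).
#'
#' @param calls Character matrix (or data frame) with 4 columns of calls
#'   `"D"`, `"T"` or `NA`.
#' @param min_k Minimum damaging calls.
#' @return Logical vector, one element per row.
#' @export
consensus_damaging <- function(calls, min_k = 2) {
  calls <- as.matrix(calls)
  if (ncol(calls) != 4) stop_format("expected 4 predictor call columns")
  rowSums(calls == "D", na.rm = TRUE) >= min_k
}

#' Allele-frequency filter
#'
#' @param exac_maf Reference-population MAF; `NA` means absent (novel).
#' @param threshold Strict upper bound for rare variants.
#' @return Character vector in `{"novel", "rare", "fail"}`: novel when the
#'   variant is absent from the reference population, rare when its MAF is
#'   strictly below `threshold`, fail otherwise (a MAF exactly at the
#'   threshold fails).
#' @export
frequency_filter <- function(exac_maf, threshold = 0.001) {
  if (any(!is.na(exac_maf) & (exac_maf < 0 | exac_maf > 1))) {
    stop_format("exac_maf must be NA or in [0, 1]")
  }
  dplyr::case_when(
    is.na(exac_maf) ~ "novel",
    exac_maf < threshold ~ "rare",
    TRUE ~ "fail"
  )
}

#' Apply the variant filtering cascade
#'
#' Three stages with per-stage accounting: (1) functional class — keep
#' loss-of-function and missense variants; (2) predictor consensus — keep
#' every loss-of-function variant and missense variants called damaging by
#' at least `min_damaging_predictors` of the four algorithms; (3) allele
#' frequency — keep variants that are novel or rarer than `maf_threshold`
#' in the reference population. Survivors are the rare deleterious variants
#' (rdSNVs) fed to the segregation stage.
#'
#' @param annotation Annotation tibble (see [read_annotation()]).
#' @param config A [filter_config()].
#' @return The retained annotation rows, with added columns `rdsnv_class`
#'   (`"lof"`/`"missense"`) and `freq_status` (`"novel"`/`"rare"`), and a
#'   funnel tibble `(stage, n_in, n_out)` as attribute `"funnel"`
#'   (accessor [funnel()]).
#' @export
filter_variants <- function(annotation, config = filter_config()) {
  stopifnot(inherits(config, "fs_filter_config"))
  ann <- tibble::as_tibble(annotation)
  n0 <- nrow(ann)
  ann$rdsnv_class <- if (n0) classify_functional(ann$functional_class) else
    character(0)
  s1 <- dplyr::filter(ann, .data$rdsnv_class %in% c("lof", "missense"))
  keep_consensus <- s1$rdsnv_class == "lof" |
    consensus_damaging(s1[predictor_columns],
                       config$min_damaging_predictors)
  s2 <- s1[keep_consensus, , drop = FALSE]
  s2$freq_status <- if (nrow(s2)) {
    frequency_filter(s2$exac_maf, config$maf_threshold)
  } else character(0)
  s3 <- dplyr::filter(s2, .data$freq_status != "fail")
  funnel <- tibble::tibble(
    stage = c("functional_class", "predictor_consensus", "allele_frequency"),
    n_in = c(n0, nrow(s1), nrow(s2)),
    n_out = c(nrow(s1), nrow(s2), nrow(s3))
  )
  structure(s3, funnel = funnel, class = c("fs_filtered", class(s3)))
}

#' Retrieve the filtering funnel of a filtered variant table
#'
#' @param x Result of [filter_variants()] or [run_pipeline()].
#' @return Tibble `(stage, n_in, n_out)`.
#' @export
funnel <- function(x) {
  attr(x, "funnel") %||% x$funnel
}
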