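#' Gene-collapsed carrier burden test
#'
#' CAST-style collapsing: an individual is a carrier when it has dosage
#' >= 1 for at least one qualifying variant in the gene. Qualifying
#' variants are the gene's co-segregating rdSNVs, optionally restricted to
#' novel alleles (no reference-population frequency). Case excess is
#' tested with a one-tailed Fisher exact test.
#'
#' @param gene Gene symbol.
#' @param segvars Segregating-variant tibble from [collect_rdsnvs()].
#' @param genotypes Dosage matrix.
#' @param case_ids,control_ids Disjoint individual id sets.
#' @param novel_only Restrict to novel variants.
#' @param annotation Annotation tibble (needed when `novel_only = TRUE`
#'   to identify novel alleles via a missing `exac_maf`).
#' @return One-row tibble `(gene, n_case_carriers, n_cases,
#'   n_control_carriers, n_controls, novel_only, p_one_tailed)`.
#' @export
collapse_burden <- function(gene, segvars, genotypes, case_ids, control_ids,
                            novel_only = FALSE, annotation = NULL) {
  if (length(intersect(case_ids, control_ids))) {
    stop_format("case and control id sets must be disjoint")
  }
  keys <- unique(segvars$variant_key[segvars$gene == gene])
  if (novel_only) {
    if (is.null(annotation)) {
      stop_format("novel_only = TRUE requires the annotation table")
    }
    novel_keys <- annotation$variant_key[is.na(annotation$exac_maf)]
    keys <- intersect(keys, novel_keys)
  }
  keys <- intersect(keys, rownames(genotypes))
  carrier_count <- function(ids) {
    if (length(keys) == 0) return(0L)
    sub <- genotypes[keys, ids, drop = FALSE]
    sum(colSums(sub >= 1, na.rm = TRUE) > 0)
  }
  a <- carrier_count(case_ids)
  c_ <- carrier_count(control_ids)
  p <- if (length(keys) == 0) 1 else {
    fisher_exact(a, length(case_ids) - a, c_, length(control_ids) - c_,
                 tail = "greater")
  }
  tibble::tibble(
    gene = gene, n_case_carriers = a, n_cases = length(case_ids),
    n_control_carriers = c_, n_controls = length(control_ids),
    novel_only = novel_only, p_one_tailed = p
  )
}

# Index cases: the first affected member of each family in template
# lineage order (the lineage starts at the youngest affected), falling
# back to pedigree order. Used to avoid pseudo-replication of a single
# transmitted allele in burden counts.
index_cases <- function(ped) {
  fams <- ped[ped$role == "family_member" & ped$status == "affected", ]
  vapply(split(fams, fams$family_id),
         function(f) f$individual_id[1], character(1))
}

#' Cohort-wide gene burden scan
#'
#' Runs [collapse_burden()] over every gene with at least one
#' co-segregating rdSNV. Cases are either one index affected per family
#' (`count_per_family = "index"`, the default, avoiding
#' pseudo-replication of transmitted alleles) or all affected individuals
#' (`"all"`); controls are the tagged population controls.
#'
#' @param cohort An `fs_cohort`.
#' @param segvars Segregating-variant tibble.
#' @param novel_only Restrict to novel alleles.
#' @param count_per_family `"index"` or `"all"`.
#' @return Object of class `fs_burden`: per-gene burden tibble sorted by
#'   p-value.
#' @export
burden_scan <- function(cohort, segvars, novel_only = FALSE,
                        count_per_family = c("index", "all")) {
  count_per_family <- match.arg(count_per_family)
  ped <- cohort$pedigree
  case_ids <- if (count_per_family == "index") {
    unname(index_cases(ped))
  } else {
    ped$individual_id[ped$role == "family_member" & ped$status == "affected"]
  }
  control_ids <- ped$individual_id[ped$role == "population_control"]
  genes <- sort(unique(segvars$gene))
  res <- purrr::map_dfr(genes, collapse_burden, segvars = segvars,
                        genotypes = cohort$variant_table$genotypes,
                        case_ids = case_ids, control_ids = control_ids,
                        novel_only = novel_only,
                        annotation = cohort$annotation)
  res <- dplyr::arrange(res, .data$p_one_tailed, .data$gene)
  structure(res, count_per_family = count_per_family,
            class = c("fs_burden", class(res)))
}

#' Rank variants by scaled CADD pathogenicity
#'
#' One row per (family, variant) among the co-segregating rdSNVs, kept
#' when scaled CADD strictly exceeds the floor, sorted by descending CADD
#' with ties broken by gene then variant key.
#'
#' @param segvars Segregating-variant tibble.
#' @param annotation Annotation tibble.
#' @param floor Strict scaled CADD floor (default 15).
#' @return Tibble `(family_id, gene, variant_key, partner_key, mode,
#'   cadd_scaled)`.
#' @export
rank_variants <- function(segvars, annotation, floor = 15) {
  segvars |>
    dplyr::select(dplyr::all_of(c("family_id", "gene", "variant_key",
                                  "partner_key", "mode"))) |>
    dplyr::inner_join(annotation[c("variant_key", "cadd_scaled")],
                      by = "variant_key") |>
    dplyr::filter(.data$cadd_scaled > floor) |>
    dplyr::arrange(dplyr::desc(.data$cadd_scaled), .data$gene,
                   .data$variant_key)
}
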