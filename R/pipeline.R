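#' Pipeline run configuration
#'
#' @param filter A [filter_config()].
#' @param segregation A [segregation_config()].
#' @param n_perm GSEA permutations.
#' @param n_bins RVIS bins.
#' @param novel_only Burden scan restricted to novel alleles.
#' @param count_per_family Burden counting convention, see [burden_scan()].
#' @param cadd_threshold High-CADD threshold.
#' @param seed Global seed (permutation null and any simulation).
#' @return Object of class `fs_run_config`.
#' @export
run_config <- function(filter = filter_config(),
                       segregation = segregation_config(),
                       n_perm = 1000, n_bins = 10,
                       novel_only = TRUE,
                       count_per_family = "index",
                       cadd_threshold = 20,
                       seed = 1) {
  structure(
    list(filter = filter, segregation = segregation, n_perm = n_perm,
         n_bins = n_bins, novel_only = novel_only,
         count_per_family = count_per_family,
         cadd_threshold = cadd_threshold, seed = seed),
    class = "fs_run_config"
  )
}

#' Load a cohort from standard files
#'
#' @param vcf,ped,annotation,rvis,gmt Paths to the cohort's VCF, PED,
#'   annotation TSV, RVIS TSV and GMT files.
#' @param gene_universe Optional explicit gene universe; defaults to the
#'   union of RVIS-table genes and annotated genes.
#' @return An `fs_cohort` (without a truth table).
#' @export
read_cohort <- function(vcf, ped, annotation, rvis, gmt,
                        gene_universe = NULL) {
  vt <- read_vcf(vcf)
  ann <- read_annotation(annotation)
  rv <- read_rvis(rvis)
  # annotation joins by exact variant key; unannotated variants dropped
  n_unannotated <- sum(!vt$variants$variant_key %in% ann$variant_key)
  if (n_unannotated) {
    message(sprintf("%d variant(s) without annotation dropped",
                    n_unannotated))
  }
  structure(
    list(
      pedigree = read_ped(ped),
      variant_table = vt,
      annotation = ann[ann$variant_key %in% vt$variants$variant_key, ],
      rvis = rv,
      gene_sets = read_gmt(gmt),
      truth = NULL,
      gene_universe = gene_universe %||% sort(union(rv$gene, ann$gene)),
      seed = NA_integer_
    ),
    class = "fs_cohort"
  )
}

#' Run the full prioritization pipeline
#'
#' Orchestrates filter, segregate, enrich, GSEA, burden and pathogenicity
#' over one cohort, optionally writing every stage output plus a JSON
#' manifest to a directory. All randomness (the GSEA permutation null) is
#' governed by the config seed, so a rerun with the same inputs and seed
#' reproduces byte-identical output tables. A stage failure aborts with
#' the stage name; the funnel accumulated so far is preserved in the
#' error condition.
#'
#' @param cohort An `fs_cohort` from [simulate_cohort()] or
#'   [read_cohort()].
#' @param config An [run_config()].
#' @param outdir Output directory, or `NULL` to skip writing.
#' @return Object of class `fs_run`: list with `filtered`, `segvars`,
#'   `enrichment`, `gsea`, `burden`, `pathogenicity`, `ranked`,
#'   `funnel` and `manifest`.
#' @export
run_pipeline <- function(cohort, config = run_config(), outdir = NULL) {
  stopifnot(inherits(cohort, "fs_cohort"))
  funnel_acc <- tibble::tibble(
    stage = "input", n_in = nrow(cohort$annotation),
    n_out = nrow(cohort$annotation)
  )
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(structure(
        class = c("fs_stage_error", "error", "condition"),
        list(message = sprintf("stage '%s' failed: %s", name,
                               conditionMessage(e)),
             call = NULL, funnel = funnel_acc)
      ))
    })
  }

  filtered <- stage("filter", filter_variants(cohort$annotation,
                                              config$filter))
  funnel_acc <- dplyr::bind_rows(funnel_acc, funnel(filtered))

  segvars <- stage("segregate",
                   collect_rdsnvs(cohort, filtered, config$segregation))
  n_rdsnv <- length(unique(segvars$variant_key))
  funnel_acc <- dplyr::bind_rows(
    funnel_acc,
    tibble::tibble(stage = "cosegregation_and_controls",
                   n_in = dplyr::last(funnel_acc$n_out), n_out = n_rdsnv)
  )

  enrichment <- stage("enrich", rvis_enrichment(
    segvars, cohort$rvis, cohort$gene_universe, n_bins = config$n_bins
  ))
  gsea <- stage("gsea", gsea_preranked(
    setNames(enrichment$zscore, enrichment$gene), cohort$gene_sets,
    weight = 1, n_perm = config$n_perm, seed = config$seed
  ))
  burden <- stage("burden", burden_scan(
    cohort, segvars, novel_only = config$novel_only,
    count_per_family = config$count_per_family
  ))
  pathogenicity <- stage("pathogenicity", cadd_pathogenicity(
    cohort, filtered, segvars, threshold = config$cadd_threshold
  ))
  ranked <- stage("rank", rank_variants(segvars, cohort$annotation,
                                        floor = config$filter$cadd_rank_floor))

  res <- structure(
    list(filtered = filtered, segvars = segvars, enrichment = enrichment,
         gsea = gsea, burden = burden, pathogenicity = pathogenicity,
         ranked = ranked, funnel = funnel_acc, manifest = NULL),
    class = "fs_run"
  )
  if (!is.null(outdir)) res$manifest <- write_run(res, cohort, config, outdir)
  res
}

flatten_segvars <- function(segvars) {
  dplyr::mutate(
    segvars,
    carriers = vapply(.data$carriers, paste, character(1), collapse = ","),
    partner_key = ifelse(is.na(.data$partner_key), ".", .data$partner_key)
  )
}

write_run <- function(res, cohort, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(outdir, name)
  readr::write_tsv(res$funnel, out("funnel.tsv"), progress = FALSE)
  readr::write_tsv(flatten_segvars(res$segvars), out("segvars.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble::as_tibble(res$enrichment), out("enrichment.tsv"),
                   progress = FALSE)
  readr::write_tsv(candidates(res$enrichment)[
    , c("gene", "rdsnv_count", "zscore", "rvis_percentile")
  ], out("candidates.tsv"), progress = FALSE)
  gsea_tbl <- dplyr::mutate(
    tibble::as_tibble(res$gsea),
    leading_edge = vapply(.data$leading_edge, paste, character(1),
                          collapse = ",")
  )
  readr::write_tsv(gsea_tbl, out("gsea.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(res$burden), out("burden.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$pathogenicity$group_compare,
                   out("cadd_group_compare.tsv"), progress = FALSE)
  readr::write_tsv(res$pathogenicity$per_set, out("cadd_per_set.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$ranked, out("ranked_variants.tsv"), progress = FALSE)
  manifest <- list(
    seed = config$seed,
    n_perm = config$n_perm,
    novel_only = config$novel_only,
    count_per_family = config$count_per_family,
    package_version = as.character(utils::packageVersion("famseg")),
    n_variants = nrow(cohort$annotation),
    n_families = length(unique(
      cohort$pedigree$family_id[cohort$pedigree$role == "family_member"]
    )),
    n_controls = sum(cohort$pedigree$role == "population_control"),
    funnel = res$funnel,
    outputs = c("funnel.tsv", "segvars.tsv", "enrichment.tsv",
                "candidates.tsv", "gsea.tsv", "burden.tsv",
                "cadd_group_compare.tsv", "cadd_per_set.tsv",
                "ranked_variants.tsv")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.fs_run <- function(x, ...) {
  cat("<fs_run>\n  funnel:\n")
  print(as.data.frame(x$funnel))
  cat(sprintf("  %d segregating rdSNV record(s), %d candidate gene(s)\n",
              nrow(x$segvars), nrow(candidates(x$enrichment))))
  cat(sprintf("  top gene set: %s (q = %.4g)\n",
              x$gsea$set[1], x$gsea$fdr_q[1]))
  invisible(x)
}
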