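functional_classes <- c("stopgain", "frameshift", "splice",
                        "nonsynonymous", "synonymous", "other")

predictor_columns <- c("sift", "polyphen2", "mutation_taster",
                       "mutation_assessor")

#' Read a GMT gene-set collection
#'
#' MSigDB dialect: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate genes within a set are dropped; empty sets
#' are a format error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) {
    stop_format("GMT set '%s' has no member genes",
                vapply(fields[bad], `[[`, character(1), 1)[1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop_format("duplicate set names in GMT")
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a per-variant annotation table
#'
#' Tab-separated with header columns `variant_key`, `gene`,
#' `functional_class`, `exac_maf`, `sift`, `polyphen2`, `mutation_taster`,
#' `mutation_assessor`, `cadd_scaled`. A `.` (or empty) `exac_maf` means
#' the variant is absent from the reference population (novel); `.`
#' predictor calls mean missing.
#'
#' @param path Path to the TSV file.
#' @return Tibble; `exac_maf` is `NA` for novel variants, predictor calls
#'   are `"D"` (damaging), `"T"` (tolerated) or `NA`.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("variant_key", "gene", "functional_class", "exac_maf",
                predictor_columns, "cadd_scaled")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols)) {
    stop_format("annotation table is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  ann <- dplyr::mutate(
    ann,
    exac_maf = as.numeric(dplyr::na_if(.data$exac_maf, ".")),
    cadd_scaled = as.numeric(.data$cadd_scaled),
    dplyr::across(dplyr::all_of(predictor_columns),
                  ~ dplyr::na_if(.x, "."))
  )
  if (any(!is.na(ann$exac_maf) & (ann$exac_maf < 0 | ann$exac_maf > 1))) {
    stop_format("exac_maf values must lie in [0, 1]")
  }
  if (!all(ann$functional_class %in% functional_classes)) {
    stop_format("unknown functional class: %s",
                setdiff(ann$functional_class, functional_classes)[1])
  }
  calls <- unlist(ann[predictor_columns])
  if (!all(calls %in% c("D", "T", NA))) {
    stop_format("predictor calls must be 'D', 'T' or '.'")
  }
  if (anyDuplicated(ann$variant_key)) {
    stop_format("each variant may have at most one annotation row")
  }
  ann
}

#' Write an annotation table as TSV
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  out <- dplyr::mutate(
    ann,
    exac_maf = ifelse(is.na(.data$exac_maf), ".",
                      format(.data$exac_maf, scientific = FALSE, trim = TRUE)),
    dplyr::across(dplyr::all_of(predictor_columns),
                  ~ ifelse(is.na(.x), ".", .x))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-level RVIS percentile table
#'
#' Tab-separated with header columns `gene` and `rvis_percentile`;
#' percentiles must lie in (0, 100] (low = intolerant).
#'
#' @param path Path to the TSV file.
#' @return Tibble `(gene, rvis_percentile)`.
#' @export
read_rvis <- function(path) {
  rvis <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  if (!all(c("gene", "rvis_percentile") %in% names(rvis))) {
    stop_format("RVIS table needs columns gene, rvis_percentile")
  }
  if (any(is.na(rvis$rvis_percentile)) ||
      any(rvis$rvis_percentile <= 0 | rvis$rvis_percentile > 100)) {
    stop_format("RVIS percentiles must lie in (0, 100]")
  }
  rvis
}

#' Write an RVIS percentile table as TSV
#'
#' @param rvis Tibble `(gene, rvis_percentile)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rvis <- function(rvis, path) {
  readr::write_tsv(rvis, path, progress = FALSE)
  invisible(path)
}
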