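#' Segregation analysis configuration
#'
#' @param strict_controls If TRUE, an in-family genotyped unaffected
#'   carrier disqualifies a dominant candidate; if FALSE (default),
#'   unaffected carriers are tolerated but flagged (incomplete penetrance).
#' @param min_affected Minimum genotyped affected members for a family to
#'   contribute dominant candidates (co-segregation is undefined with one
#'   affected); families below it contribute only compound-het candidates.
#' @param include_compound_het Detect compound-heterozygous pairs in
#'   parent-parent-proband constellations.
#' @return Object of class `fs_segregation_config`.
#' @export
segregation_config <- function(strict_controls = FALSE,
                               min_affected = 2,
                               include_compound_het = TRUE) {
  structure(
    list(strict_controls = strict_controls, min_affected = min_affected,
         include_compound_het = include_compound_het),
    class = "fs_segregation_config"
  )
}

#' Dominant co-segregation test for one variant in one family
#'
#' A variant co-segregates under the dominant model when every genotyped
#' affected family member carries at least one alternate allele
#' (heterozygous or homozygous), and — with `strict_controls = TRUE` — no
#' genotyped unaffected member carries it. With `strict_controls = FALSE`
#' unaffected carriers are tolerated but reported via
#' `unaffected_carriers_present`.
#'
#' @param dosage Named dosage vector (names = individual ids) for the
#'   family's members; `NA` = not genotyped.
#' @param family Pedigree tibble rows for one family.
#' @param strict_controls See [segregation_config()].
#' @return List with `cosegregates` (TRUE/FALSE, or NA when no affected is
#'   genotyped — not evaluable), `carriers` (ids) and
#'   `unaffected_carriers_present`.
#' @export
cosegregates_dominant <- function(dosage, family, strict_controls = FALSE) {
  aff <- family$individual_id[family$status == "affected"]
  unaff <- family$individual_id[family$status == "unaffected"]
  d_aff <- dosage[aff]
  genotyped_aff <- aff[!is.na(d_aff)]
  if (length(genotyped_aff) == 0) {
    return(list(cosegregates = NA, carriers = character(0),
                unaffected_carriers_present = NA))
  }
  all_aff_carry <- all(dosage[genotyped_aff] >= 1)
  d_unaff <- dosage[unaff]
  unaff_carriers <- unaff[!is.na(d_unaff) & d_unaff >= 1]
  ok <- all_aff_carry && (!strict_controls || length(unaff_carriers) == 0)
  carriers <- names(dosage)[!is.na(dosage) & dosage >= 1]
  list(
    cosegregates = ok,
    carriers = if (ok) carriers else character(0),
    unaffected_carriers_present = length(unaff_carriers) > 0
  )
}

#' Compound-heterozygote pair detection for one gene in one
#' parent-parent-proband constellation
#'
#' Returns unordered pairs of variants in the same gene for which the
#' proband is heterozygous for both, one variant is carried (among the
#' parents) by the mother only and the other by the father only. Pairs on
#' the same parental haplotype (cis: both from one parent) are excluded —
#' they segregate as a single dominant unit. Parental origin is determined
#' from parental genotypes; a variant for which either parent is
#' ungenotyped is not evaluable and is skipped, as is the whole analysis
#' when a parent is missing from the pedigree.
#'
#' @param gene_variants Variant keys of one gene to consider.
#' @param proband,father,mother Individual ids.
#' @param genotypes Dosage matrix (rows = variant keys).
#' @return Tibble with columns `variant_key`, `partner_key`,
#'   `maternal_key`, `paternal_key`; zero rows when no valid pair exists
#'   or the constellation is not evaluable.
#' @export
compound_het_pairs <- function(gene_variants, proband, father, mother,
                               genotypes) {
  empty <- tibble::tibble(variant_key = character(0),
                          partner_key = character(0),
                          maternal_key = character(0),
                          paternal_key = character(0))
  if (is.na(father) || is.na(mother) ||
      !all(c(proband, father, mother) %in% colnames(genotypes))) {
    return(empty)
  }
  keys <- intersect(gene_variants, rownames(genotypes))
  if (length(keys) < 2) return(empty)
  g <- genotypes[keys, c(proband, father, mother), drop = FALSE]
  evaluable <- !is.na(g[, father]) & !is.na(g[, mother]) & !is.na(g[, proband])
  het <- evaluable & g[, proband] == 1
  maternal <- het & g[, mother] >= 1 & g[, father] == 0
  paternal <- het & g[, father] >= 1 & g[, mother] == 0
  mk <- keys[maternal]
  pk <- keys[paternal]
  if (!length(mk) || !length(pk)) return(empty)
  pairs <- expand.grid(maternal_key = mk, paternal_key = pk,
                       stringsAsFactors = FALSE)
  tibble::tibble(
    variant_key = pmin(pairs$maternal_key, pairs$paternal_key),
    partner_key = pmax(pairs$maternal_key, pairs$paternal_key),
    maternal_key = pairs$maternal_key,
    paternal_key = pairs$paternal_key
  )
}

#' Remove candidates carried by in-cohort population controls
#'
#' Drops any segregating variant for which at least one tagged
#' phenotype-confirmed population control carries the alternate allele;
#' for compound-het rows the partner variant is checked too. Removal
#' counts are reported via a message.
#'
#' @param segvars Segregating-variant tibble (see [collect_rdsnvs()]).
#' @param genotypes Dosage matrix.
#' @param control_ids Individual ids of tagged population controls.
#' @return Filtered `segvars`.
#' @export
exclude_cohort_controls <- function(segvars, genotypes, control_ids) {
  if (length(control_ids) == 0 || nrow(segvars) == 0) return(segvars)
  cg <- genotypes[, intersect(control_ids, colnames(genotypes)),
                  drop = FALSE]
  in_controls <- rowSums(cg >= 1, na.rm = TRUE) > 0
  carried <- rownames(cg)[in_controls]
  drop <- segvars$variant_key %in% carried |
    (!is.na(segvars$partner_key) & segvars$partner_key %in% carried)
  if (any(drop)) {
    message(sprintf("excluded %d candidate(s) carried by controls",
                    sum(drop)))
  }
  segvars[!drop, , drop = FALSE]
}

#' Collect co-segregating rare deleterious variants across a cohort
#'
#' Unions, over all families, the dominant co-segregating variants
#' (families with at least `min_affected` genotyped affecteds) and
#' compound-heterozygous pairs (affected probands with both parents
#' genotyped), then removes candidates carried by in-cohort population
#' controls. Output order is deterministic: family, gene, variant key.
#'
#' @param cohort An `fs_cohort` (or list with `pedigree` and
#'   `variant_table`).
#' @param filtered Filtered annotation tibble from [filter_variants()].
#' @param config A [segregation_config()].
#' @return Tibble with columns `family_id`, `gene`, `variant_key`,
#'   `partner_key` (NA for dominant rows), `mode`, `carriers` (list
#'   column) and `unaffected_carriers_present`.
#' @export
collect_rdsnvs <- function(cohort, filtered,
                           config = segregation_config()) {
  ped <- cohort$pedigree
  g <- cohort$variant_table$genotypes
  keys <- intersect(filtered$variant_key, rownames(g))
  gene_of <- setNames(filtered$gene, filtered$variant_key)
  fams <- ped[ped$role == "family_member", ]
  out <- list()
  gk <- g[keys, , drop = FALSE]
  for (fam_id in unique(fams$family_id)) {
    fam <- fams[fams$family_id == fam_id, ]
    aff <- fam$individual_id[fam$status == "affected"]
    unaff <- fam$individual_id[fam$status == "unaffected"]
    # dominant model, vectorised over variants
    if (length(aff) >= config$min_affected) {
      ga <- gk[, aff, drop = FALSE]
      n_gt_aff <- rowSums(!is.na(ga))
      all_carry <- rowSums(ga >= 1, na.rm = TRUE) == n_gt_aff & n_gt_aff > 0
      gu <- gk[, unaff, drop = FALSE]
      has_unaff_carrier <- rowSums(gu >= 1, na.rm = TRUE) > 0
      hit <- all_carry & (!config$strict_controls | !has_unaff_carrier)
      for (key in keys[hit]) {
        dos <- gk[key, fam$individual_id]
        out[[length(out) + 1]] <- tibble::tibble(
          family_id = fam_id, gene = unname(gene_of[key]),
          variant_key = key, partner_key = NA_character_,
          mode = "dominant",
          carriers = list(names(dos)[!is.na(dos) & dos >= 1]),
          unaffected_carriers_present = has_unaff_carrier[key]
        )
      }
    }
    # compound-het model for affected probands with both parents present
    if (config$include_compound_het) {
      probands <- fam[fam$status == "affected" & !is.na(fam$father_id) &
                        !is.na(fam$mother_id), ]
      for (i in seq_len(nrow(probands))) {
        pr <- probands[i, ]
        d_pr <- gk[, pr$individual_id]
        het_keys <- keys[!is.na(d_pr) & d_pr == 1]
        het_genes <- gene_of[het_keys]
        candidate_genes <- names(which(table(het_genes) >= 2))
        for (gene in candidate_genes) {
          pairs <- compound_het_pairs(
            keys[gene_of[keys] == gene], pr$individual_id,
            pr$father_id, pr$mother_id, gk
          )
          for (j in seq_len(nrow(pairs))) {
            for (key in c(pairs$variant_key[j], pairs$partner_key[j])) {
              partner <- setdiff(c(pairs$variant_key[j],
                                   pairs$partner_key[j]), key)
              dos <- gk[key, fam$individual_id]
              out[[length(out) + 1]] <- tibble::tibble(
                family_id = fam_id, gene = gene, variant_key = key,
                partner_key = partner, mode = "compound_het",
                carriers = list(names(dos)[!is.na(dos) & dos >= 1]),
                unaffected_carriers_present = FALSE
              )
            }
          }
        }
      }
    }
  }
  segvars <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    family_id = character(0), gene = character(0),
    variant_key = character(0), partner_key = character(0),
    mode = character(0), carriers = list(),
    unaffected_carriers_present = logical(0)
  )
  segvars <- dplyr::distinct(
    segvars, .data$family_id, .data$variant_key, .data$partner_key,
    .keep_all = TRUE
  )
  control_ids <- ped$individual_id[ped$role == "population_control"]
  segvars <- exclude_cohort_controls(segvars, g, control_ids)
  dplyr::arrange(segvars, .data$family_id, .data$gene, .data$variant_key)
}
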