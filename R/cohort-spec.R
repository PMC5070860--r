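# Pedigree templates. Each template lists members with parental links, a
# founder flag, sex, and an "affection lineage": the order in which members
# are marked affected as affected_per_family grows. The lineage is a single
# descent path from one founder so that a fully penetrant dominant variant
# can co-segregate through every affected.
pedigree_templates <- list(
  trio = list(
    members = tibble::tibble(
      id = c("FA", "MO", "CH"),
      father = c(NA, NA, "FA"),
      mother = c(NA, NA, "MO"),
      sex = c(1L, 2L, NA)
    ),
    lineage = c("CH", "FA"),
    founder_origin = "FA",
    proband = "CH"
  ),
  three_generation = list(
    members = tibble::tibble(
      id = c("GF", "GM", "P1", "SP", "C1", "C2"),
      father = c(NA, NA, "GF", NA, "P1", "P1"),
      mother = c(NA, NA, "GM", NA, "SP", "SP"),
      sex = c(1L, 2L, 1L, 2L, NA, NA)
    ),
    lineage = c("C1", "P1", "GF"),
    founder_origin = "GF",
    proband = "C1"
  ),
  extended = list(
    members = tibble::tibble(
      id = c("GF", "GM", "P1", "S1", "P2", "S2", "C1", "C2"),
      father = c(NA, NA, "GF", NA, "GF", NA, "P1", "P2"),
      mother = c(NA, NA, "GM", NA, "GM", NA, "S1", "S2"),
      sex = c(1L, 2L, 1L, 2L, 2L, 1L, NA, NA)
    ),
    lineage = c("C1", "P1", "GF", "P2", "C2"),
    founder_origin = "GF",
    proband = "C1"
  )
)

#' Specify a synthetic family cohort's pedigree structure
#'
#' The default mix (42 trios, 8 three-generation families, 1 extended
#' family) yields 51 families totalling 182 individuals, the scale of a
#' typical multiplex whole-exome cohort.
#'
#' @param n_families Total number of families; must equal `sum(structures)`.
#' @param structures Named integer vector of per-template family counts;
#'   names must be among `"trio"`, `"three_generation"`, `"extended"`.
#' @param affected_per_family Number of affected members per family
#'   (>= 2 so that co-segregation is defined); capped at each template's
#'   affection-lineage length.
#' @param seed Integer seed.
#' @return Object of class `fs_pedigree_spec`.
#' @export
pedigree_spec <- function(n_families = 51,
                          structures = c(trio = 42, three_generation = 8,
                                         extended = 1),
                          affected_per_family = 2,
                          seed = 1) {
  unknown <- setdiff(names(structures), names(pedigree_templates))
  if (length(unknown)) {
    stop_format("unknown pedigree template(s): %s",
                paste(unknown, collapse = ", "))
  }
  if (sum(structures) != n_families) {
    stop_format("sum(structures) (%d) must equal n_families (%d)",
                sum(structures), n_families)
  }
  if (affected_per_family < 1) {
    stop_format("affected_per_family must be >= 1")
  }
  structure(
    list(n_families = n_families, structures = structures,
         affected_per_family = affected_per_family, seed = seed),
    class = "fs_pedigree_spec"
  )
}

#' Specify the background (non-causal) variation model
#'
#' Governs the neutral variant load the filtering cascade must work
#' through: how many sites per gene, the reference-population allele
#' frequency spectrum, the background scaled-CADD law, and how often each
#' pathogenicity predictor calls a variant damaging given its CADD tier.
#'
#' @param n_genes Size of the gene universe.
#' @param variants_per_gene_rate Poisson mean of sites per gene.
#' @param maf_spectrum Mixture weights over frequency tiers `novel`
#'   (absent from the reference population), `rare` (< 0.1%),
#'   `low_frequency` (0.1-5%), `common` (> 5%); must sum to 1.
#' @param novel_cohort_freq Cohort allele frequency used to drop genotypes
#'   at novel sites (the reference MAF is undefined for them); the default
#'   is singleton scale for ~375 diploid individuals.
#' @param cadd_exp_mean Mean of the exponential bulk of background scaled
#'   CADD.
#' @param cadd_tail_prob,cadd_tail_range Weight and (low, high) support of
#'   the heavy uniform tail of background scaled CADD.
#' @param predictor_concordance Named probabilities that a predictor calls
#'   a variant damaging given its CADD tier (`low` < 10, `mid` 10-20,
#'   `high` > 20).
#' @param missing_call_rate Probability a predictor call is missing.
#' @return Object of class `fs_background_spec`.
#' @export
background_spec <- function(n_genes = 1200,
                            variants_per_gene_rate = 3,
                            maf_spectrum = c(novel = 0.05, rare = 0.25,
                                             low_frequency = 0.30,
                                             common = 0.40),
                            novel_cohort_freq = 0.0013,
                            cadd_exp_mean = 6,
                            cadd_tail_prob = 0.05,
                            cadd_tail_range = c(15, 35),
                            predictor_concordance = c(low = 0.10, mid = 0.35,
                                                      high = 0.70),
                            missing_call_rate = 0.05) {
  if (abs(sum(maf_spectrum) - 1) > 1e-08) {
    stop_format("maf_spectrum weights must sum to 1")
  }
  probs <- c(maf_spectrum, cadd_tail_prob, predictor_concordance,
             missing_call_rate)
  if (any(probs < 0 | probs > 1)) {
    stop_format("all probabilities must lie in [0, 1]")
  }
  required <- c("novel", "rare", "low_frequency", "common")
  if (!setequal(names(maf_spectrum), required)) {
    stop_format("maf_spectrum must name tiers %s",
                paste(required, collapse = ", "))
  }
  structure(
    list(n_genes = n_genes,
         variants_per_gene_rate = variants_per_gene_rate,
         maf_spectrum = maf_spectrum[required],
         novel_cohort_freq = novel_cohort_freq,
         cadd_exp_mean = cadd_exp_mean,
         cadd_tail_prob = cadd_tail_prob,
         cadd_tail_range = cadd_tail_range,
         predictor_concordance = predictor_concordance,
         missing_call_rate = missing_call_rate),
    class = "fs_background_spec"
  )
}

#' Specify the causal-variant planting model
#'
#' Describes the disease architecture the simulator injects: which genes
#' carry causal alleles, the gene set ("pathway") that collects them, the
#' inheritance mode, penetrance, the fraction of families planted, and how
#' pathogenic the causal alleles look to the annotation layer.
#'
#' @param causal_genes Gene symbols receiving planted variants.
#' @param pathway_set Name of the gene set containing the causal genes.
#' @param inheritance `"dominant"` or `"compound_het"`.
#' @param penetrance Probability that an affected carries the planted
#'   allele.
#' @param fraction_families_planted Fraction of families receiving a plant.
#' @param causal_cadd_range (low, high) scaled CADD bounds for planted
#'   alleles.
#' @param causal_maf Reference-population MAF of planted alleles; 0 means
#'   novel (absent from the reference population).
#' @return Object of class `fs_plant_spec`.
#' @export
plant_spec <- function(causal_genes = paste0("G", sprintf("%04d", 1:6)),
                       pathway_set = "NOTCH_SIGNALING",
                       inheritance = c("dominant", "compound_het"),
                       penetrance = 1,
                       fraction_families_planted = 12 / 51,
                       causal_cadd_range = c(25, 35),
                       causal_maf = 0) {
  inheritance <- match.arg(inheritance)
  if (penetrance < 0 || penetrance > 1) {
    stop_format("penetrance must lie in [0, 1]")
  }
  if (fraction_families_planted < 0 || fraction_families_planted > 1) {
    stop_format("fraction_families_planted must lie in [0, 1]")
  }
  structure(
    list(causal_genes = causal_genes, pathway_set = pathway_set,
         inheritance = inheritance, penetrance = penetrance,
         fraction_families_planted = fraction_families_planted,
         causal_cadd_range = causal_cadd_range, causal_maf = causal_maf),
    class = "fs_plant_spec"
  )
}
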