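# Shared fixtures, all built in code.

# A five-member, two-generation pedigree: founder couple, two children,
# one grandchild by an untyped... no: spouse omitted, child2 x child1? Keep
# a simple nuclear family of 5: parents + 3 children.
nuclear5 <- function(affected = c("CH1", "CH2"), family_id = "FAM1") {
  ids <- c("FA", "MO", "CH1", "CH2", "CH3")
  tibble::tibble(
    family_id = family_id,
    individual_id = ids,
    father_id = c(NA, NA, "FA", "FA", "FA"),
    mother_id = c(NA, NA, "MO", "MO", "MO"),
    sex = c(1L, 2L, 1L, 2L, 1L),
    status = ifelse(ids %in% affected, "affected", "unaffected"),
    role = "family_member"
  )
}

trio_ped <- function(family_id = "FAM1", affected = "CH") {
  ids <- c("FA", "MO", "CH")
  fid <- family_id
  tibble::tibble(
    family_id = fid,
    individual_id = paste0(fid, "_", ids),
    father_id = c(NA, NA, paste0(fid, "_FA")),
    mother_id = c(NA, NA, paste0(fid, "_MO")),
    sex = c(1L, 2L, 1L),
    status = ifelse(ids %in% affected, "affected", "unaffected"),
    role = "family_member"
  )
}

# Minimal annotation row builder.
make_annotation <- function(n, gene = sprintf("G%04d", seq_len(n)),
                            functional_class = "nonsynonymous",
                            exac_maf = NA_real_, cadd = 25,
                            calls = c("D", "D", "T", "T")) {
  tibble::tibble(
    variant_key = sprintf("chr1:%d:A:G", seq_len(n)),
    gene = rep_len(gene, n),
    functional_class = rep_len(functional_class, n),
    exac_maf = rep_len(exac_maf, n),
    sift = rep_len(calls[1], n),
    polyphen2 = rep_len(calls[2], n),
    mutation_taster = rep_len(calls[3], n),
    mutation_assessor = rep_len(calls[4], n),
    cadd_scaled = rep_len(cadd, n)
  )
}

# A small cohort for pipeline-level tests: quick but structurally complete.
small_cohort <- function(seed = 1) {
  simulate_cohort(
    pedigrees = pedigree_spec(
      n_families = 10,
      structures = c(trio = 8, three_generation = 2)
    ),
    background = background_spec(n_genes = 200),
    plant = plant_spec(
      causal_genes = sprintf("G%04d", 1:2),
      fraction_families_planted = 0.4
    ),
    n_controls = 40,
    seed = seed
  )
}
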