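test_that("pedigree templates expand correctly", {
  spec <- pedigree_spec(n_families = 1, structures = c(trio = 1), seed = 2)
  ped <- simulate_pedigrees(spec)
  expect_equal(nrow(ped), 3)
  founders <- ped[is.na(ped$father_id) & is.na(ped$mother_id), ]
  expect_equal(nrow(founders), 2)
  child <- ped[!is.na(ped$father_id), ]
  expect_equal(nrow(child), 1)
  expect_true(all(c(child$father_id, child$mother_id) %in%
                    founders$individual_id))
  expect_error(pedigree_spec(structures = c(quartet = 51)), "unknown")
  expect_error(pedigree_spec(n_families = 5, structures = c(trio = 4)),
               "must equal")
})

test_that("pedigree generation is seed-deterministic (byte-identical PED)", {
  spec <- pedigree_spec(seed = 7)
  p1 <- withr::local_tempfile(fileext = ".ped")
  p2 <- withr::local_tempfile(fileext = ".ped")
  write_ped(simulate_pedigrees(spec), p1)
  write_ped(simulate_pedigrees(spec), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("parent links are complete and consistent in deep pedigrees", {
  ped <- simulate_pedigrees(pedigree_spec(
    n_families = 6, structures = c(three_generation = 4, extended = 2)
  ))
  # exhaustive parent-link walk: every named parent exists in-family and
  # ancestry terminates at founders
  for (i in seq_len(nrow(ped))) {
    fam <- ped[ped$family_id == ped$family_id[i], ]
    for (parent in c(ped$father_id[i], ped$mother_id[i])) {
      if (!is.na(parent)) expect_true(parent %in% fam$individual_id)
    }
  }
  expect_silent(validate_pedigree <- famseg:::validate_pedigree(ped))
  # default affection assignment gives each family >= 2 affected
  n_aff <- table(ped$family_id[ped$status == "affected"])
  expect_true(all(n_aff >= 2))
})

test_that("gene dropping respects degenerate allele frequencies", {
  ped <- nuclear5()
  g0 <- gene_drop(ped, rep(0, 5), seed = 1)
  expect_true(all(g0 == 0))
  g1 <- gene_drop(ped, rep(1, 5), seed = 1)
  expect_true(all(g1 == 2))
})

test_that("founder allele frequency is binomially calibrated", {
  ped <- trio_ped("F1")
  n_sites <- 10000
  g <- gene_drop(ped, rep(0.1, n_sites), seed = 42)
  founder_freq <- mean(g[, c("F1_FA", "F1_MO")]) / 2
  se <- sqrt(0.1 * 0.9 / (2 * 2 * n_sites))
  expect_lt(abs(founder_freq - 0.1), 3 * se)
})

test_that("gene dropping never produces Mendelian violations", {
  ped <- simulate_pedigrees(pedigree_spec(
    n_families = 4,
    structures = c(trio = 2, three_generation = 1, extended = 1)
  ))
  g <- gene_drop(ped, runif(400, 0, 0.5), seed = 3)
  nonfounders <- ped[!is.na(ped$father_id), ]
  for (i in seq_len(nrow(nonfounders))) {
    child <- g[, nonfounders$individual_id[i]]
    fa <- g[, nonfounders$father_id[i]]
    mo <- g[, nonfounders$mother_id[i]]
    # each transmitted allele must exist in the corresponding parent
    expect_true(all(child <= (fa >= 1) + (mo >= 1) + pmax(fa - 1, 0) +
                      pmax(mo - 1, 0)))
    expect_true(all(child >= (fa == 2) + (mo == 2)))
  }
})

test_that("fully penetrant dominant plants make every affected a carrier", {
  co <- simulate_cohort(
    pedigrees = pedigree_spec(n_families = 5,
                              structures = c(three_generation = 5),
                              affected_per_family = 3),
    background = background_spec(n_genes = 100),
    plant = plant_spec(causal_genes = "G0001", penetrance = 1,
                       fraction_families_planted = 1),
    n_controls = 10, seed = 11
  )
  g <- co$variant_table$genotypes
  for (key in unique(co$truth$variant_key)) {
    fam_id <- co$truth$family_id[co$truth$variant_key == key][1]
    fam <- co$pedigree[co$pedigree$family_id == fam_id, ]
    aff <- fam$individual_id[fam$status == "affected"]
    expect_true(all(g[key, aff] >= 1))
  }
})

test_that("plant penetrance is binomially calibrated for independent affecteds", {
  # siblings are transmission-independent given the founder origin, so the
  # affected-carrier fraction should match the penetrance
  n_fam <- 200
  ped <- dplyr::bind_rows(lapply(seq_len(n_fam), function(i) {
    nuclear5(affected = c("CH1", "CH2", "CH3"),
             family_id = sprintf("F%03d", i)) |>
      dplyr::mutate(individual_id = paste0(family_id, "_", individual_id),
                    father_id = ifelse(is.na(father_id), NA,
                                       paste0(family_id, "_", father_id)),
                    mother_id = ifelse(is.na(mother_id), NA,
                                       paste0(family_id, "_", mother_id)),
                    template = "nuclear")
  }))
  bg <- background_spec(n_genes = 20, variants_per_gene_rate = 1)
  vt <- drop_genotypes(ped, bg, seed = 5)
  res <- suppressWarnings(plant_causal(
    ped, vt,
    plant_spec(causal_genes = "G0001", penetrance = 0.5,
               fraction_families_planted = 1),
    seed = 5
  ))
  g <- res$variants$genotypes
  aff_ids <- ped$individual_id[ped$status == "affected"]
  carrier <- vapply(seq_len(n_fam), function(i) {
    fam_id <- sprintf("F%03d", i)
    key <- res$truth$variant_key[res$truth$family_id == fam_id][1]
    g[key, paste0(fam_id, "_", c("CH1", "CH2", "CH3"))] >= 1
  }, logical(3))
  frac <- mean(carrier)
  se <- sqrt(0.5 * 0.5 / length(carrier))
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("compound-het plants give the proband one allele from each parent", {
  co <- simulate_cohort(
    pedigrees = pedigree_spec(n_families = 4, structures = c(trio = 4)),
    background = background_spec(n_genes = 50),
    plant = plant_spec(causal_genes = "G0001",
                       inheritance = "compound_het",
                       fraction_families_planted = 1),
    n_controls = 5, seed = 13
  )
  g <- co$variant_table$genotypes
  truth <- co$truth
  for (fam_id in unique(truth$family_id)) {
    keys <- unique(truth$variant_key[truth$family_id == fam_id])
    expect_length(keys, 2)
    pro <- paste0(fam_id, "_CH")
    fa <- paste0(fam_id, "_FA")
    mo <- paste0(fam_id, "_MO")
    expect_equal(unname(g[keys, pro]), c(1L, 1L))
    # exactly one parental carrier per variant, one from each side
    parent_carriers <- cbind(g[keys, fa] >= 1, g[keys, mo] >= 1)
    expect_equal(rowSums(parent_carriers), c(1, 1), ignore_attr = TRUE)
    expect_equal(colSums(parent_carriers), c(1, 1), ignore_attr = TRUE)
  }
})

test_that("truth table and genotype matrix agree on planted carriers", {
  co <- small_cohort(seed = 17)
  g <- co$variant_table$genotypes
  truth <- co$truth[co$truth$flag != "unreachable_affected", ]
  # every recorded carrier has the allele
  for (i in seq_len(nrow(truth))) {
    expect_gte(g[truth$variant_key[i], truth$individual_id[i]], 1)
  }
  # and every allele at a planted site is a recorded carrier
  for (key in unique(truth$variant_key)) {
    carriers <- colnames(g)[g[key, ] >= 1]
    expect_setequal(carriers, truth$individual_id[truth$variant_key == key])
  }
})

test_that("annotation respects causal tiers and degenerate settings", {
  co <- simulate_cohort(
    pedigrees = pedigree_spec(n_families = 4, structures = c(trio = 4)),
    background = background_spec(n_genes = 50),
    plant = plant_spec(causal_genes = "G0001",
                       fraction_families_planted = 1,
                       causal_cadd_range = c(25, 25), causal_maf = 0),
    n_controls = 5, seed = 19
  )
  causal_keys <- unique(co$truth$variant_key)
  ann <- co$annotation[co$annotation$variant_key %in% causal_keys, ]
  expect_true(all(ann$cadd_scaled == 25))
  expect_true(all(is.na(ann$exac_maf))) # causal_maf = 0 means novel
  calls <- as.matrix(ann[c("sift", "polyphen2", "mutation_taster",
                           "mutation_assessor")])
  expect_true(all(rowSums(calls == "D", na.rm = TRUE) >= 2))
})

test_that("cohort simulation is seed-reproducible byte-for-byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(small_cohort(seed = 23), d1)
  write_cohort(small_cohort(seed = 23), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("default cohort matches the study-scale design", {
  ped <- simulate_pedigrees(pedigree_spec())
  expect_equal(length(unique(ped$family_id)), 51)
  expect_equal(nrow(ped), 182)
  ctrl <- simulate_controls(193, seed = 1)
  expect_equal(nrow(ctrl), 193)
  expect_true(all(ctrl$role == "population_control"))
})
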