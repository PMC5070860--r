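burden_fixture <- function(n_case = 106, n_control = 193,
                           case_carriers = 3, control_carriers = 0) {
  case_ids <- paste0("CASE", seq_len(n_case))
  control_ids <- paste0("CTRL", seq_len(n_control))
  g <- matrix(0L, nrow = 2, ncol = n_case + n_control,
              dimnames = list(c("v1", "v2"), c(case_ids, control_ids)))
  if (case_carriers > 0) g["v1", case_ids[seq_len(case_carriers)]] <- 1L
  if (control_carriers > 0) {
    g["v1", control_ids[seq_len(control_carriers)]] <- 1L
  }
  sv <- tibble::tibble(gene = "GENE1", variant_key = "v1",
                       family_id = "F1", partner_key = NA_character_,
                       mode = "dominant")
  list(g = g, sv = sv, case_ids = case_ids, control_ids = control_ids)
}

test_that("collapsed burden reproduces the 3-vs-0 carrier worked example", {
  fx <- burden_fixture()
  res <- collapse_burden("GENE1", fx$sv, fx$g, fx$case_ids, fx$control_ids)
  expect_equal(res$n_case_carriers, 3)
  expect_equal(res$n_control_carriers, 0)
  expect_equal(res$p_one_tailed, (106 * 105 * 104) / (299 * 298 * 297),
               tolerance = 1e-09)
})

test_that("collapsed burden handles empty genes and novel-only filtering", {
  fx <- burden_fixture()
  res <- collapse_burden("GENE_ABSENT", fx$sv, fx$g, fx$case_ids,
                         fx$control_ids)
  expect_equal(res$n_case_carriers, 0)
  expect_equal(res$p_one_tailed, 1)
  ann <- make_annotation(1)
  ann$variant_key <- "v1"
  ann$exac_maf <- 5e-04 # rare but not novel
  res2 <- collapse_burden("GENE1", fx$sv, fx$g, fx$case_ids, fx$control_ids,
                          novel_only = TRUE, annotation = ann)
  expect_equal(res2$n_case_carriers, 0) # the only variant is not novel
  expect_error(collapse_burden("GENE1", fx$sv, fx$g, c("X", "Y"),
                               c("Y", "Z")), "disjoint")
})

test_that("carrier counts equal a boolean-reduction oracle on random genotypes", {
  set.seed(81)
  ids <- paste0("I", 1:60)
  keys <- paste0("v", 1:8)
  g <- matrix(rbinom(8 * 60, 2, 0.15), nrow = 8,
              dimnames = list(keys, ids))
  sv <- tibble::tibble(gene = "G", variant_key = keys,
                       family_id = "F1", partner_key = NA_character_,
                       mode = "dominant")
  res <- collapse_burden("G", sv, g, ids[1:30], ids[31:60])
  oracle <- apply(g >= 1, 2, any)
  expect_equal(res$n_case_carriers, sum(oracle[1:30]))
  expect_equal(res$n_control_carriers, sum(oracle[31:60]))
})

test_that("burden obeys monotonicity and label-swap symmetry", {
  fx <- burden_fixture(case_carriers = 4, control_carriers = 2)
  ann <- make_annotation(2)
  ann$variant_key <- c("v1", "v2")
  ann$exac_maf <- c(NA, 5e-04)
  all_rare <- collapse_burden("GENE1", fx$sv, fx$g, fx$case_ids,
                              fx$control_ids)
  novel <- collapse_burden("GENE1", fx$sv, fx$g, fx$case_ids,
                           fx$control_ids, novel_only = TRUE,
                           annotation = ann)
  expect_lte(novel$n_case_carriers, all_rare$n_case_carriers)
  # swapped labels with tail greater equal the original tail less
  a <- all_rare$n_case_carriers; n1 <- all_rare$n_cases
  c_ <- all_rare$n_control_carriers; n2 <- all_rare$n_controls
  expect_equal(
    fisher_exact(c_, n2 - c_, a, n1 - a, tail = "greater"),
    fisher_exact(a, n1 - a, c_, n2 - c_, tail = "less"),
    tolerance = 1e-12
  )
})

test_that("burden_scan counts one index case per family by default", {
  co <- small_cohort(seed = 83)
  f <- filter_variants(co$annotation)
  sv <- suppressMessages(collect_rdsnvs(co, f))
  bu <- burden_scan(co, sv, novel_only = TRUE)
  n_fam <- length(unique(
    co$pedigree$family_id[co$pedigree$role == "family_member"]
  ))
  expect_true(all(bu$n_cases == n_fam))
  bu_all <- burden_scan(co, sv, count_per_family = "all")
  n_aff <- sum(co$pedigree$status == "affected" &
                 co$pedigree$role == "family_member")
  expect_true(all(bu_all$n_cases == n_aff))
  expect_s3_class(glance(bu), "tbl_df")
})

test_that("CADD group comparison behaves at the null and under shift", {
  s <- list(a = c(1, 5, 9, 13, 2, 6), b = c(1, 5, 9, 13, 2, 6))
  res <- cadd_group_compare(s)
  expect_gte(res$p_wilcoxon, 0.9)
  set.seed(85)
  shifted <- list(cases = rnorm(50, 10), controls = rnorm(50, 0))
  res2 <- cadd_group_compare(shifted)
  expect_lt(res2$p_wilcoxon, 1e-06)
  tiny <- list(a = 1, b = c(2, 3))
  expect_true(is.na(cadd_group_compare(tiny)$p_wilcoxon))
})

test_that("high-CADD fraction test uses a strict threshold", {
  s <- list(cases = c(25, 21, 10, 20), controls = c(5, 20, 18, 3))
  res <- high_cadd_fraction_test(s, threshold = 20)
  # a score of exactly 20 does not exceed the threshold
  expect_equal(unname(res$fractions["cases"]), 0.5)
  expect_equal(unname(res$fractions["controls"]), 0)
  # degenerate: nothing exceeds in either group
  res2 <- high_cadd_fraction_test(list(a = c(1, 2), b = c(3, 4)),
                                  threshold = 20)
  expect_equal(res2$tests$statistic, 0)
  expect_equal(res2$tests$p_chisq, 1)
  # closed-form check via the shared 2x2 machinery
  s3 <- list(a = c(rep(25, 20), rep(5, 80)), b = c(rep(25, 10), rep(5, 90)))
  res3 <- high_cadd_fraction_test(s3)
  expect_equal(round(res3$tests$statistic, 3), 3.922)
})

test_that("per-set CADD enrichment recovers a planted shift and respects BH", {
  set.seed(87)
  genes <- sprintf("G%03d", 1:60)
  sets <- c(list(TARGET = genes[1:10]),
            setNames(lapply(1:9, function(i) sample(genes[11:60], 10)),
                     paste0("S", 1:9)))
  hits <- 0
  for (i in 1:25) {
    case_v <- tibble::tibble(
      gene = sample(genes, 240, replace = TRUE),
      cadd_scaled = rexp(240, 1 / 6)
    )
    in_target <- case_v$gene %in% sets$TARGET
    case_v$cadd_scaled[in_target] <- case_v$cadd_scaled[in_target] + 8
    ctrl_v <- tibble::tibble(
      gene = sample(genes, 240, replace = TRUE),
      cadd_scaled = rexp(240, 1 / 6)
    )
    res <- per_set_cadd_enrichment(case_v, ctrl_v, sets)
    if (res$set[1] == "TARGET" && res$fdr_q[1] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.9)
  # single-set collection: q equals the nominal p
  res1 <- per_set_cadd_enrichment(case_v, ctrl_v, sets["TARGET"])
  expect_equal(res1$fdr_q, res1$p_wilcoxon)
})

test_that("null per-set enrichment yields essentially no discoveries", {
  set.seed(89)
  genes <- sprintf("G%03d", 1:60)
  sets <- setNames(lapply(1:10, function(i) sample(genes, 10)),
                   paste0("S", 1:10))
  n_disc <- vapply(1:25, function(i) {
    case_v <- tibble::tibble(gene = sample(genes, 100, replace = TRUE),
                             cadd_scaled = rexp(100, 1 / 6))
    ctrl_v <- tibble::tibble(gene = sample(genes, 100, replace = TRUE),
                             cadd_scaled = rexp(100, 1 / 6))
    sum(per_set_cadd_enrichment(case_v, ctrl_v, sets)$fdr_q < 0.05)
  }, numeric(1))
  expect_equal(median(n_disc), 0)
})

test_that("variant ranking filters strictly and sorts deterministically", {
  sv <- tibble::tibble(
    family_id = c("F1", "F1", "F2", "F2"),
    gene = c("GA", "GB", "GA", "GC"),
    variant_key = c("v1", "v2", "v3", "v4"),
    partner_key = NA_character_,
    mode = "dominant"
  )
  ann <- make_annotation(4)
  ann$variant_key <- paste0("v", 1:4)
  ann$cadd_scaled <- c(30, 15, 22, 22)
  rk <- rank_variants(sv, ann, floor = 15)
  # CADD exactly 15 is excluded; ties broken by gene then key
  expect_equal(rk$variant_key, c("v1", "v3", "v4"))
  expect_true(all(diff(rk$cadd_scaled) <= 0))
  expect_equal(nrow(rank_variants(sv, dplyr::mutate(ann, cadd_scaled = 10))),
               0)
  # sort-then-filter oracle on a random table
  set.seed(91)
  sv2 <- tibble::tibble(
    family_id = sample(c("F1", "F2"), 50, replace = TRUE),
    gene = sample(c("GA", "GB", "GC"), 50, replace = TRUE),
    variant_key = paste0("w", 1:50),
    partner_key = NA_character_, mode = "dominant"
  )
  ann2 <- make_annotation(50)
  ann2$variant_key <- sv2$variant_key
  ann2$cadd_scaled <- round(runif(50, 5, 35), 1)
  rk2 <- rank_variants(sv2, ann2)
  oracle <- merge(sv2, ann2[c("variant_key", "cadd_scaled")])
  oracle <- oracle[oracle$cadd_scaled > 15, ]
  oracle <- oracle[order(-oracle$cadd_scaled, oracle$gene,
                         oracle$variant_key), ]
  expect_equal(rk2$variant_key, oracle$variant_key)
})

test_that("cohort pathogenicity report separates planted cases from controls", {
  co <- small_cohort(seed = 93)
  f <- filter_variants(co$annotation)
  sv <- suppressMessages(collect_rdsnvs(co, f))
  pa <- cadd_pathogenicity(co, f, sv)
  cmp <- pa$group_compare
  cc <- cmp[cmp$group1 == "cases" & cmp$group2 == "controls", ]
  expect_gt(cc$median1, cc$median2)
  expect_s3_class(autoplot(pa), "ggplot")
})
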