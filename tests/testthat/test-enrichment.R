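make_segvars <- function(df) {
  df$partner_key <- df$partner_key %||% NA_character_
  df$mode <- df$mode %||% "dominant"
  df$carriers <- df$carriers %||% replicate(nrow(df), character(0),
                                            simplify = FALSE)
  df$unaffected_carriers_present <- FALSE
  df
}

test_that("gene counts are unique-variant counts over the universe", {
  universe <- sprintf("G%02d", 1:5)
  expect_equal(gene_counts(tibble::tibble(gene = character(0),
                                          variant_key = character(0)),
                           universe)$rdsnv_count, rep(0L, 5))
  # the same variant in two families counts once
  sv <- tibble::tibble(
    gene = c("G01", "G01", "G02"),
    variant_key = c("v1", "v1", "v2"),
    family_id = c("F1", "F2", "F1")
  )
  counts <- gene_counts(sv, universe)
  expect_equal(counts$rdsnv_count[counts$gene == "G01"], 1L)
  # random segvars vs an independent group-by oracle
  set.seed(51)
  sv2 <- tibble::tibble(
    gene = sample(universe, 60, replace = TRUE),
    variant_key = paste0("v", sample(30, 60, replace = TRUE)),
    family_id = sample(c("F1", "F2", "F3"), 60, replace = TRUE)
  )
  sv2$variant_key <- paste(sv2$gene, sv2$variant_key) # key within gene
  oracle <- tapply(sv2$variant_key, sv2$gene,
                   function(k) length(unique(k)))
  counts2 <- gene_counts(sv2, universe)
  for (g in names(oracle)) {
    expect_equal(counts2$rdsnv_count[counts2$gene == g],
                 unname(oracle[g]), ignore_attr = TRUE)
  }
  expect_message(
    gene_counts(tibble::tibble(gene = "NOT_THERE", variant_key = "v",
                               family_id = "F1"), universe),
    "outside the declared universe"
  )
})

test_that("z-scores use the population standard deviation over the universe", {
  counts <- tibble::tibble(gene = sprintf("G%04d", 1:1000),
                           rdsnv_count = c(10L, rep(0L, 999)))
  z <- gene_zscores(counts)
  mu <- 10 / 1000
  sd_pop <- sqrt(mean((counts$rdsnv_count - mu)^2))
  expect_equal(z$zscore[1], (10 - mu) / sd_pop, tolerance = 1e-12)
  expect_equal(mean(z$zscore), 0, tolerance = 1e-09)
  expect_equal(sqrt(mean(z$zscore^2)), 1, tolerance = 1e-09)
  # gene at the mean has z = 0
  counts2 <- tibble::tibble(gene = c("A", "B", "C"),
                            rdsnv_count = c(1L, 2L, 3L))
  expect_equal(gene_zscores(counts2)$zscore[2], 0)
  expect_error(gene_zscores(tibble::tibble(gene = c("A", "B"),
                                           rdsnv_count = c(1L, 1L))),
               "undefined")
})

test_that("RVIS binning uses right-closed decile intervals", {
  counts <- tibble::tibble(gene = c("A", "B", "C", "D"),
                           rdsnv_count = 0L)
  rvis <- tibble::tibble(gene = c("A", "B", "C"),
                         rvis_percentile = c(5, 100, 10))
  binned <- suppressMessages(bin_by_rvis(counts, rvis))
  expect_equal(binned$rvis_bin, c(1L, 10L, 1L, NA))
  # uniform percentiles fill bins evenly (multinomial bound)
  set.seed(55)
  n <- 10000
  counts_u <- tibble::tibble(gene = as.character(1:n), rdsnv_count = 0L)
  rvis_u <- tibble::tibble(gene = as.character(1:n),
                           rvis_percentile = runif(n, 1e-09, 100))
  occ <- table(bin_by_rvis(counts_u, rvis_u)$rvis_bin)
  se <- sqrt(n * 0.1 * 0.9)
  expect_true(all(abs(occ - n / 10) < 3 * se))
})

test_that("extreme-bin excess test matches the exact Wilcoxon tail", {
  # bin 1 counts all strictly larger than the interior: one-sided
  # p = 1 / choose(15, 5)
  binned <- tibble::tibble(
    gene = as.character(1:16),
    rdsnv_count = c(rep(10L, 5), rep(0L, 11)),
    rvis_bin = c(rep(1L, 5), rep(2:9, length.out = 10), 10L)
  )
  res <- extreme_bin_excess_test(binned, mode = "exact")
  expect_equal(res$p_low, 1 / choose(15, 5), tolerance = 1e-12)
  # identical distributions: no excess signal
  binned2 <- tibble::tibble(
    gene = as.character(1:30),
    rdsnv_count = rep(c(0L, 1L, 2L), 10),
    rvis_bin = rep(1:10, each = 3)
  )
  res2 <- extreme_bin_excess_test(binned2)
  expect_gte(res2$p_low, 0.4)
  expect_gte(res2$p_high, 0.4)
})

test_that("a planted intolerant-bin excess is detected reliably", {
  set.seed(61)
  hits <- 0
  n_sim <- 100
  for (i in seq_len(n_sim)) {
    counts <- rpois(5000, 0.05)
    bins <- rep(1:10, each = 500)
    excess_idx <- sample(which(bins == 1), 50)
    counts[excess_idx] <- counts[excess_idx] + 2L
    binned <- tibble::tibble(gene = as.character(1:5000),
                             rdsnv_count = counts, rvis_bin = bins)
    if (extreme_bin_excess_test(binned)$p_low < 0.01) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("candidate calling applies both strict gates", {
  enr <- tibble::tibble(
    gene = c("A", "B", "C", "D"),
    zscore = c(2.0, 5, 2.5, 8),
    rvis_percentile = c(5, 50, 9, 10)
  )
  cands <- call_candidates(enr)
  expect_equal(cands$gene, c("D", "C")) # descending z
  # z = 2 exactly fails the strict gate; percentile 50 fails intolerance
  expect_false("A" %in% cands$gene)
  expect_false("B" %in% cands$gene)
  # predicate oracle on random tables
  set.seed(63)
  enr2 <- tibble::tibble(gene = as.character(1:500),
                         zscore = rnorm(500, 1, 1.5),
                         rvis_percentile = runif(500, 1e-06, 100))
  oracle <- enr2$gene[enr2$zscore > 2 & enr2$rvis_percentile <= 10]
  expect_setequal(call_candidates(enr2)$gene, oracle)
})

test_that("GSEA reproduces the hand-computed toy running sum", {
  ranking <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2)
  res <- gsea_preranked(ranking, list(TOY = c("g1", "g3")), weight = 1,
                        n_perm = 50, seed = 1)
  # N_R = |3| + |1| = 4; running sum 0.75, 0.4167, 0.6667, 0.3333, 0
  expect_equal(res$es[res$set == "TOY"], 0.75, tolerance = 1e-12)
  expect_equal(res$leading_edge[[1]], "g1")
})

test_that("GSEA degenerate whole-universe set matches the direct curve", {
  set.seed(65)
  ranking <- setNames(rnorm(40), paste0("g", 1:40))
  res <- gsea_preranked(ranking, list(ALL = names(ranking)), n_perm = 20,
                        seed = 2)
  s <- sort(ranking, decreasing = TRUE)
  curve <- cumsum(abs(s)) / sum(abs(s))
  expect_equal(res$es, max(curve), tolerance = 1e-12)
})

test_that("GSEA ES is invariant to positive scaling at weight 1", {
  set.seed(67)
  ranking <- setNames(rnorm(100), paste0("g", 1:100))
  sets <- list(S = sample(names(ranking), 12))
  e1 <- gsea_preranked(ranking, sets, n_perm = 10, seed = 3)$es
  e2 <- gsea_preranked(ranking * 7.5, sets, n_perm = 10, seed = 3)$es
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("GSEA is deterministic under a fixed seed", {
  set.seed(69)
  ranking <- setNames(rnorm(200), paste0("g", 1:200))
  sets <- list(A = sample(names(ranking), 10),
               B = sample(names(ranking), 10))
  r1 <- gsea_preranked(ranking, sets, n_perm = 100, seed = 11)
  r2 <- gsea_preranked(ranking, sets, n_perm = 100, seed = 11)
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))
  r3 <- gsea_preranked(ranking, sets, n_perm = 100, seed = 12)
  expect_false(identical(r1$p_nominal, r3$p_nominal) &&
                 identical(r1$nes, r3$nes))
})

test_that("GSEA enrichment scores agree with fgsea", {
  skip_if_not_installed("fgsea")
  set.seed(71)
  ranking <- setNames(rnorm(300), paste0("g", 1:300))
  ranking <- ranking[order(-ranking)] # fgsea expects sorted stats
  sets <- lapply(1:5, function(i) sample(names(ranking), 20))
  names(sets) <- paste0("S", 1:5)
  ours <- gsea_preranked(ranking, sets, weight = 1, n_perm = 10, seed = 1)
  ref <- suppressWarnings(
    fgsea::fgsea(sets, ranking, nperm = 100, gseaParam = 1)
  )
  for (s in names(sets)) {
    expect_equal(ours$es[ours$set == s], ref$ES[ref$pathway == s],
                 tolerance = 1e-06)
  }
})

test_that("GSEA warns on and skips sets outside the universe", {
  ranking <- setNames(rnorm(50), paste0("g", 1:50))
  expect_warning(
    res <- gsea_preranked(ranking,
                          list(IN = c("g1", "g2"), OUT = c("x1", "x2")),
                          n_perm = 10, seed = 1),
    "skipping"
  )
  expect_equal(res$set, "IN")
  expect_error(
    suppressWarnings(gsea_preranked(ranking, list(OUT = "x1"),
                                    n_perm = 10, seed = 1)),
    "no gene set"
  )
})

test_that("rvis_enrichment wrapper ties the pieces together", {
  co <- small_cohort(seed = 73)
  f <- filter_variants(co$annotation)
  sv <- suppressMessages(collect_rdsnvs(co, f))
  enr <- rvis_enrichment(sv, co$rvis, co$gene_universe)
  expect_s3_class(enr, "fs_enrichment")
  expect_equal(nrow(enr), length(co$gene_universe))
  expect_true(all(candidates(enr)$zscore > 2))
  gl <- glance(enr)
  expect_equal(gl$n_candidates, nrow(candidates(enr)))
  p <- autoplot(enr)
  expect_s3_class(p, "ggplot")
})
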