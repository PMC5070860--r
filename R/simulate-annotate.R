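background_class_probs <- c(
  nonsynonymous = 0.60, synonymous = 0.25, stopgain = 0.02,
  frameshift = 0.02, splice = 0.01, other = 0.10
)

cadd_tier <- function(cadd) {
  dplyr::case_when(cadd > 20 ~ "high", cadd >= 10 ~ "mid", TRUE ~ "low")
}

#' Annotate a simulated variant table
#'
#' Emulates the annotation layer of an exome pipeline. Background variants
#' get a functional class from a fixed class mix, their reference-population
#' MAF from the site tier (novel sites have none), scaled CADD from the
#' background law, and four predictor calls whose damaging probability
#' follows the CADD tier (so predictors and CADD agree imperfectly, as in
#' real data). Planted causal variants are nonsynonymous, draw scaled CADD
#' from the plant's causal range, carry the plant's MAF (none when novel)
#' and always have at least two damaging predictor calls.
#'
#' @param variants [fs_variants] from [plant_causal()] or
#'   [drop_genotypes()] (its `variants` tibble must carry `gene`, `tier`,
#'   `exac_maf`).
#' @param bg A [background_spec()].
#' @param plant A [plant_spec()] (used for the causal CADD range).
#' @param seed Integer seed.
#' @return Annotation tibble (see [read_annotation()] for columns).
#' @export
annotate_cohort <- function(variants, bg, plant = plant_spec(), seed = 1) {
  v <- variants$variants
  n <- nrow(v)
  with_seed(derive_seed(seed, "annotate"), {
    causal <- v$tier == "causal"
    functional_class <- sample(names(background_class_probs), n,
                               replace = TRUE, prob = background_class_probs)
    functional_class[causal] <- "nonsynonymous"
    cadd <- ifelse(
      runif(n) < bg$cadd_tail_prob,
      runif(n, bg$cadd_tail_range[1], bg$cadd_tail_range[2]),
      stats::rexp(n, rate = 1 / bg$cadd_exp_mean)
    )
    cadd[causal] <- runif(sum(causal), plant$causal_cadd_range[1],
                          plant$causal_cadd_range[2])
    p_damaging <- bg$predictor_concordance[cadd_tier(cadd)]
    calls <- matrix(NA_character_, n, 4,
                    dimnames = list(NULL, predictor_columns))
    for (j in 1:4) {
      u <- runif(n)
      call_j <- ifelse(runif(n) < p_damaging, "D", "T")
      call_j[u < bg$missing_call_rate] <- NA_character_
      calls[, j] <- call_j
    }
    if (any(causal)) {
      for (j in 1:4) {
        cc <- ifelse(runif(sum(causal)) < 0.9, "D", "T")
        calls[causal, j] <- cc
      }
      calls[causal, 1:2] <- "D" # consensus guaranteed for causal alleles
    }
    tibble::tibble(
      variant_key = v$variant_key,
      gene = v$gene,
      functional_class = functional_class,
      exac_maf = v$exac_maf,
      sift = calls[, "sift"],
      polyphen2 = calls[, "polyphen2"],
      mutation_taster = calls[, "mutation_taster"],
      mutation_assessor = calls[, "mutation_assessor"],
      cadd_scaled = round(cadd, 3)
    )
  })
}

#' Simulate gene-level RVIS percentiles
#'
#' Percentiles are a random permutation of an even grid over (0, 100];
#' designated intolerant genes (typically the causal genes) are swapped
#' into the bottom decile, mirroring the observation that dominant disease
#' genes concentrate among the most intolerant genes genome-wide.
#'
#' @param genes Gene universe.
#' @param intolerant_genes Genes forced into the bottom RVIS decile.
#' @param seed Integer seed.
#' @return Tibble `(gene, rvis_percentile)`.
#' @export
simulate_rvis <- function(genes, intolerant_genes = character(0), seed = 1) {
  with_seed(derive_seed(seed, "rvis"), {
    n <- length(genes)
    perc <- 100 * sample.int(n) / n
    names(perc) <- genes
    for (g in intolerant_genes) {
      if (perc[g] > 10) {
        pool <- names(perc)[perc <= 10 & !(names(perc) %in% intolerant_genes)]
        swap <- sample(pool, 1)
        tmp <- perc[g]
        perc[g] <- perc[swap]
        perc[swap] <- tmp
      }
    }
    tibble::tibble(gene = genes, rvis_percentile = unname(perc[genes]))
  })
}

#' Simulate a hallmark-style gene-set collection
#'
#' Draws `n_sets` random sets of `set_size` genes; the designated pathway
#' set contains the causal genes plus random members, so the causal signal
#' is confined to one named set while others may overlap it by chance.
#'
#' @param genes Gene universe.
#' @param causal_genes Genes placed in the designated set.
#' @param pathway_set Name of the designated set.
#' @param n_sets,set_size Collection dimensions.
#' @param seed Integer seed.
#' @return Named list of character vectors.
#' @export
simulate_gene_sets <- function(genes, causal_genes = character(0),
                               pathway_set = "NOTCH_SIGNALING",
                               n_sets = 50, set_size = 25, seed = 1) {
  with_seed(derive_seed(seed, "gene_sets"), {
    sets <- lapply(seq_len(n_sets - 1), function(i) {
      sort(sample(genes, set_size))
    })
    names(sets) <- sprintf("SET%02d", seq_len(n_sets - 1))
    filler <- sample(setdiff(genes, causal_genes),
                     max(0, set_size - length(causal_genes)))
    sets[[pathway_set]] <- sort(c(causal_genes, filler))
    sets[order(names(sets) != pathway_set)]
  })
}

#' Simulate a complete family cohort
#'
#' One-call generator producing everything the pipeline consumes: family
#' pedigrees plus unrelated population controls, background genotypes by
#' Mendelian gene dropping, planted causal variants with a truth table, an
#' annotation table, gene-level RVIS percentiles and a gene-set collection.
#'
#' @param pedigrees A [pedigree_spec()].
#' @param background A [background_spec()].
#' @param plant A [plant_spec()], or `NULL` for a plant-free cohort.
#' @param n_controls Number of unrelated population controls.
#' @param seed Integer seed governing every random draw.
#' @return Object of class `fs_cohort`: a list with elements `pedigree`,
#'   `variant_table` ([fs_variants]), `annotation`, `rvis`, `gene_sets`,
#'   `truth`, `gene_universe` and `seed`.
#' @export
simulate_cohort <- function(pedigrees = pedigree_spec(),
                            background = background_spec(),
                            plant = plant_spec(),
                            n_controls = 193,
                            seed = 1) {
  pedigrees$seed <- seed
  ped <- dplyr::bind_rows(
    simulate_pedigrees(pedigrees),
    simulate_controls(n_controls, seed = seed)
  )
  vt <- drop_genotypes(ped, background, seed = seed)
  if (!is.null(plant)) {
    planted <- plant_causal(
      ped, vt, plant, seed = seed,
      gene_universe = sprintf("G%04d", seq_len(background$n_genes))
    )
    vt <- planted$variants
    truth <- planted$truth
  } else {
    truth <- tibble::tibble(
      variant_key = character(0), gene = character(0),
      family_id = character(0), individual_id = character(0),
      mode = character(0), flag = character(0)
    )
  }
  ann <- annotate_cohort(vt, background, plant %||% plant_spec(), seed = seed)
  genes <- sprintf("G%04d", seq_len(background$n_genes))
  causal <- if (is.null(plant)) character(0) else plant$causal_genes
  rvis <- simulate_rvis(genes, intolerant_genes = causal, seed = seed)
  sets <- simulate_gene_sets(
    genes, causal_genes = causal,
    pathway_set = if (is.null(plant)) "NOTCH_SIGNALING" else plant$pathway_set,
    seed = seed
  )
  structure(
    list(pedigree = ped, variant_table = vt, annotation = ann, rvis = rvis,
         gene_sets = sets, truth = truth, gene_universe = genes,
         seed = seed),
    class = "fs_cohort"
  )
}

#' @export
print.fs_cohort <- function(x, ...) {
  n_fam <- length(unique(x$pedigree$family_id[x$pedigree$role == "family_member"]))
  cat(sprintf(
    "<fs_cohort> %d families (%d members), %d controls, %d variants, %d genes\n",
    n_fam, sum(x$pedigree$role == "family_member"),
    sum(x$pedigree$role == "population_control"),
    nrow(x$variant_table$variants), length(x$gene_universe)
  ))
  cat(sprintf("  planted: %d causal variants in %d families\n",
              length(unique(x$truth$variant_key)),
              length(unique(x$truth$family_id))))
  invisible(x)
}

#' Write all cohort artifacts to a directory
#'
#' Emits the standard file formats: `cohort.vcf`, `cohort.ped`,
#' `annotation.tsv`, `rvis.tsv`, `gene_sets.gmt` and `truth.tsv`.
#'
#' @param cohort An `fs_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$variant_table, file.path(dir, "cohort.vcf"))
  write_ped(cohort$pedigree, file.path(dir, "cohort.ped"))
  write_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_rvis(cohort$rvis, file.path(dir, "rvis.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
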