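#' Drop genotypes through pedigrees at given site frequencies
#'
#' Mendelian gene dropping: founder genotypes are drawn from Hardy-Weinberg
#' proportions at each site's allele frequency; every non-founder receives
#' one allele from each parent, each transmitted allele chosen uniformly
#' from the parent's two. No Mendelian violations are possible by
#' construction.
#'
#' @param ped Pedigree tibble (see [simulate_pedigrees()]).
#' @param maf Numeric vector of per-site alternate-allele frequencies.
#' @param seed Integer seed.
#' @return Integer dosage matrix, `length(maf)` rows by individuals.
#' @export
gene_drop <- function(ped, maf, seed = 1) {
  if (nrow(ped) == 0) stop_format("pedigree is empty")
  if (any(maf < 0 | maf > 1)) stop_format("allele frequencies must be in [0, 1]")
  n_sites <- length(maf)
  with_seed(derive_seed(seed, "gene_drop"), {
    ord <- topological_order(ped)
    g <- matrix(0L, nrow = n_sites, ncol = nrow(ped),
                dimnames = list(NULL, ped$individual_id))
    parent_lookup <- ped[match(ord, ped$individual_id), ]
    for (i in seq_along(ord)) {
      id <- ord[i]
      fa <- parent_lookup$father_id[i]
      mo <- parent_lookup$mother_id[i]
      if (is.na(fa) && is.na(mo)) {
        g[, id] <- rbinom(n_sites, 2L, maf)
      } else {
        from_f <- rbinom(n_sites, 1L, g[, fa] / 2)
        from_m <- rbinom(n_sites, 1L, g[, mo] / 2)
        g[, id] <- from_f + from_m
      }
    }
    g[, ped$individual_id, drop = FALSE]
  })
}

# Background site table: genes laid out in blocks of 100 kb along chr1-22,
# sites per gene ~ Poisson(rate), frequency tier from the MAF spectrum.
generate_sites <- function(bg, seed) {
  with_seed(derive_seed(seed, "sites"), {
    genes <- sprintf("G%04d", seq_len(bg$n_genes))
    n_per_gene <- rpois(bg$n_genes, bg$variants_per_gene_rate)
    gene_of <- rep(genes, n_per_gene)
    gene_idx <- rep(seq_len(bg$n_genes), n_per_gene)
    n <- length(gene_of)
    tier <- sample(names(bg$maf_spectrum), n, replace = TRUE,
                   prob = bg$maf_spectrum)
    exac_maf <- dplyr::case_when(
      tier == "novel" ~ NA_real_,
      tier == "rare" ~ runif(n, 1e-05, 1e-03),
      tier == "low_frequency" ~ runif(n, 1e-03, 0.05),
      tier == "common" ~ runif(n, 0.05, 0.5)
    )
    cohort_freq <- ifelse(tier == "novel", bg$novel_cohort_freq, exac_maf)
    chrom <- paste0("chr", (gene_idx - 1L) %% 22L + 1L)
    offset <- unlist(lapply(n_per_gene[n_per_gene > 0], function(k) {
      sort(sample.int(99999L, k))
    }))
    pos <- ((gene_idx - 1L) %/% 22L) * 100000L + offset
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    sites <- tibble::tibble(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = unname(alt),
      gene = gene_of, tier = tier, exac_maf = exac_maf,
      cohort_freq = cohort_freq
    )
    sites$variant_key <- variant_key(sites$chrom, sites$pos, sites$ref,
                                     sites$alt)
    sites <- sites[!duplicated(sites$variant_key), ]
    sort_variants(sites)
  })
}

#' Simulate background genotypes for a cohort
#'
#' Generates the background site table from a [background_spec()] and drops
#' genotypes through the pedigrees (controls are founders and draw directly
#' from Hardy-Weinberg). Novel sites (no reference-population frequency)
#' segregate at the spec's singleton-scale cohort frequency.
#'
#' @param ped Pedigree tibble including any controls.
#' @param bg A [background_spec()].
#' @param seed Integer seed.
#' @return An [fs_variants] object whose `variants` tibble carries `gene`,
#'   `tier`, `exac_maf` and `cohort_freq` columns for the annotation stage.
#' @export
drop_genotypes <- function(ped, bg, seed = 1) {
  sites <- generate_sites(bg, seed)
  g <- gene_drop(ped, sites$cohort_freq, seed = derive_seed(seed, "background"))
  fs_variants(
    sites[c("variant_key", "chrom", "pos", "ref", "alt", "gene", "tier",
            "exac_maf", "cohort_freq")],
    g
  )
}
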