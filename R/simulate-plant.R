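# Descendant sets per founder, used to choose the founder lineage through
# which a planted allele enters a family.
family_descendants <- function(fam) {
  kids_of <- function(ids) {
    fam$individual_id[fam$father_id %in% ids | fam$mother_id %in% ids]
  }
  founders <- fam$individual_id[is.na(fam$father_id) & is.na(fam$mother_id)]
  desc <- list()
  for (f in founders) {
    d <- f
    frontier <- f
    while (length(frontier)) {
      frontier <- setdiff(kids_of(frontier), d)
      d <- c(d, frontier)
    }
    desc[[f]] <- d
  }
  desc
}

# Walk from `id` up to `top` along parents that are descendants of `top`.
path_to_founder <- function(fam, id, top, desc_top) {
  path <- id
  cur <- id
  while (cur != top) {
    row <- fam[fam$individual_id == cur, ]
    nxt <- c(row$father_id, row$mother_id)
    nxt <- nxt[!is.na(nxt) & nxt %in% desc_top]
    if (!length(nxt)) break
    cur <- nxt[1]
    path <- c(path, cur)
  }
  path
}

plant_dominant_family <- function(fam, penetrance) {
  affected <- fam$individual_id[fam$status == "affected"]
  drawn <- affected[runif(length(affected)) < penetrance]
  desc <- family_descendants(fam)
  covered <- vapply(desc, function(d) sum(drawn %in% d), integer(1))
  top <- names(desc)[which.max(covered)]
  if (length(drawn) && covered[top] < length(drawn)) {
    warning(sprintf(
      "family %s: affected members in disjoint founder lineages; %s",
      fam$family_id[1], "best-effort plant (see truth table flags)"
    ), call. = FALSE)
  }
  reachable <- drawn[drawn %in% desc[[top]]]
  forced <- unique(unlist(lapply(reachable, path_to_founder, fam = fam,
                                 top = top, desc_top = desc[[top]])))
  if (!length(reachable)) forced <- top
  carriers <- union(forced, reachable)
  # Mendelian chance transmission to unaffected off-path descendants
  ord <- topological_order(fam)
  status_of <- setNames(fam$status, fam$individual_id)
  chance <- character(0)
  for (id in ord) {
    if (id %in% carriers || id %in% chance) next
    if (status_of[id] == "affected") next # penetrance draw already decided
    row <- fam[fam$individual_id == id, ]
    parents <- c(row$father_id, row$mother_id)
    parents <- parents[!is.na(parents)]
    if (any(parents %in% c(carriers, chance)) && runif(1) < 0.5) {
      chance <- c(chance, id)
    }
  }
  all_carriers <- union(carriers, chance)
  flag <- dplyr::case_when(
    all_carriers %in% drawn ~ "",
    status_of[all_carriers] == "affected" ~ "forced_carrier",
    TRUE ~ "unaffected_carrier"
  )
  unreachable <- setdiff(drawn, reachable)
  list(carriers = all_carriers, flags = flag, unreachable = unreachable)
}

# Allocate a fresh site in the gene's coordinate block that does not
# collide with existing keys.
new_site_in_gene <- function(gene, existing_keys) {
  idx <- as.integer(sub("^G", "", gene))
  chrom <- paste0("chr", (idx - 1L) %% 22L + 1L)
  base <- ((idx - 1L) %/% 22L) * 100000L
  repeat {
    pos <- base + sample.int(99999L, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    key <- variant_key(chrom, pos, ref, alt)
    if (!(key %in% existing_keys)) {
      return(tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            variant_key = key))
    }
  }
}

#' Plant causal variants into a simulated cohort
#'
#' Injects family-specific causal alleles on top of the background
#' genotypes. Under the dominant model each planted family receives one
#' causal variant in its assigned gene, entering through a single founder
#' lineage: every affected carries the allele with probability
#' `penetrance`, ancestors on the descent path are carriers (unaffected
#' ones are flagged), and unaffected off-path descendants of carriers may
#' inherit the allele with Mendelian probability 1/2. Under the
#' compound-heterozygous model the family's proband carries two variants in
#' the assigned gene, one inherited from each parent.
#'
#' @param ped Pedigree tibble (families plus controls).
#' @param variants Background [fs_variants] from [drop_genotypes()].
#' @param plant A [plant_spec()].
#' @param seed Integer seed.
#' @param gene_universe All genes under study; defaults to the genes with
#'   background sites (causal genes need not have any).
#' @return List with `variants` (background plus planted rows, re-sorted)
#'   and `truth` (tibble `variant_key`, `gene`, `family_id`,
#'   `individual_id`, `mode`, `flag`, one row per planted carrier).
#' @export
plant_causal <- function(ped, variants, plant, seed = 1,
                         gene_universe = NULL) {
  stopifnot(inherits(plant, "fs_plant_spec"))
  gene_universe <- gene_universe %||% unique(variants$variants$gene)
  missing_genes <- setdiff(plant$causal_genes, gene_universe)
  if (length(missing_genes)) {
    stop_format("causal gene(s) not in the gene universe: %s",
                paste(missing_genes, collapse = ", "))
  }
  fams <- ped[ped$role == "family_member", ]
  fam_ids <- unique(fams$family_id)
  n_plant <- round(plant$fraction_families_planted * length(fam_ids))
  with_seed(derive_seed(seed, "plant"), {
    planted_fams <- sort(sample(fam_ids, n_plant))
    gene_of_fam <- setNames(
      rep(plant$causal_genes, length.out = n_plant), planted_fams
    )
    all_ids <- colnames(variants$genotypes)
    new_rows <- list()
    new_geno <- list()
    truth <- list()
    keys <- variants$variants$variant_key
    add_variant <- function(gene, carriers1, fam_id, mode, flags) {
      site <- new_site_in_gene(gene, keys)
      keys <<- c(keys, site$variant_key)
      dos <- setNames(rep(0L, length(all_ids)), all_ids)
      dos[carriers1] <- 1L
      new_rows[[length(new_rows) + 1]] <<- dplyr::mutate(
        site, gene = gene, tier = "causal",
        exac_maf = if (plant$causal_maf == 0) NA_real_ else plant$causal_maf,
        cohort_freq = NA_real_
      )
      new_geno[[length(new_geno) + 1]] <<- dos
      truth[[length(truth) + 1]] <<- tibble::tibble(
        variant_key = site$variant_key, gene = gene, family_id = fam_id,
        individual_id = carriers1, mode = mode, flag = flags
      )
      site$variant_key
    }
    for (fam_id in planted_fams) {
      fam <- fams[fams$family_id == fam_id, ]
      gene <- gene_of_fam[[fam_id]]
      if (plant$inheritance == "dominant") {
        res <- plant_dominant_family(fam, plant$penetrance)
        key <- add_variant(gene, res$carriers, fam_id = fam_id,
                           mode = "dominant", flags = res$flags)
        if (length(res$unreachable)) {
          truth[[length(truth) + 1]] <- tibble::tibble(
            variant_key = key, gene = gene, family_id = fam_id,
            individual_id = res$unreachable, mode = "dominant",
            flag = "unreachable_affected"
          )
        }
      } else {
        tmpl <- pedigree_templates[[fam$template[1]]]
        proband <- paste0(fam_id, "_", tmpl$proband)
        prow <- fam[fam$individual_id == proband, ]
        mother <- prow$mother_id
        father <- prow$father_id
        add_variant(gene, c(mother, proband), fam_id = fam_id,
                    mode = "compound_het",
                    flags = c("maternal_origin", "maternal_origin"))
        add_variant(gene, c(father, proband), fam_id = fam_id,
                    mode = "compound_het",
                    flags = c("paternal_origin", "paternal_origin"))
      }
    }
    if (!length(new_rows)) {
      return(list(variants = variants,
                  truth = tibble::tibble(
                    variant_key = character(0), gene = character(0),
                    family_id = character(0), individual_id = character(0),
                    mode = character(0), flag = character(0)
                  )))
    }
    planted_tbl <- dplyr::bind_rows(new_rows)
    planted_g <- do.call(rbind, new_geno)
    merged_v <- dplyr::bind_rows(variants$variants, planted_tbl)
    merged_g <- rbind(variants$genotypes, planted_g)
    ord <- order(chrom_rank(merged_v$chrom), merged_v$pos, merged_v$ref,
                 merged_v$alt)
    list(
      variants = fs_variants(merged_v[ord, ], merged_g[ord, , drop = FALSE]),
      truth = dplyr::bind_rows(truth)
    )
  })
}
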