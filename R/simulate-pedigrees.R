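#' Simulate a set of family pedigrees
#'
#' Expands the requested template mix into a pedigree tibble. Founders have
#' no parents; children's sexes are drawn at random (sex is carried but the
#' analysis is autosomal-only). Affection statuses follow each template's
#' descent lineage: the first `affected_per_family` members of the lineage
#' are affected, all others unaffected.
#'
#' @param spec An [pedigree_spec()] object.
#' @return Pedigree tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `status`, `role`, `template`.
#' @export
simulate_pedigrees <- function(spec) {
  stopifnot(inherits(spec, "fs_pedigree_spec"))
  with_seed(derive_seed(spec$seed, "pedigrees"), {
    template_of <- rep(names(spec$structures), spec$structures)
    fams <- purrr::imap(template_of, function(tmpl_name, i) {
      tmpl <- pedigree_templates[[tmpl_name]]
      fam_id <- sprintf("F%02d", i)
      m <- tmpl$members
      k <- min(spec$affected_per_family, length(tmpl$lineage))
      affected <- tmpl$lineage[seq_len(k)]
      sex <- m$sex
      sex[is.na(sex)] <- sample(1:2, sum(is.na(sex)), replace = TRUE)
      tibble::tibble(
        family_id = fam_id,
        individual_id = paste0(fam_id, "_", m$id),
        father_id = ifelse(is.na(m$father), NA_character_,
                           paste0(fam_id, "_", m$father)),
        mother_id = ifelse(is.na(m$mother), NA_character_,
                           paste0(fam_id, "_", m$mother)),
        sex = sex,
        status = ifelse(m$id %in% affected, "affected", "unaffected"),
        role = "family_member",
        template = tmpl_name
      )
    })
    ped <- dplyr::bind_rows(fams)
    validate_pedigree(ped)
    ped
  })
}

#' Simulate unrelated population controls
#'
#' Controls are singleton "families" drawn from the same background model
#' as the family cohort, with no planted variants, mirroring the role of an
#' external phenotype-confirmed control panel.
#'
#' @param n_controls Number of controls.
#' @param seed Integer seed.
#' @return Pedigree tibble of unaffected singletons tagged
#'   `role = "population_control"`.
#' @export
simulate_controls <- function(n_controls = 193, seed = 1) {
  with_seed(derive_seed(seed, "controls"), {
    tibble::tibble(
      family_id = sprintf("CTRL%03d", seq_len(n_controls)),
      individual_id = sprintf("CTRL%03d_1", seq_len(n_controls)),
      father_id = NA_character_,
      mother_id = NA_character_,
      sex = sample(1:2, n_controls, replace = TRUE),
      status = "unaffected",
      role = "population_control",
      template = "singleton"
    )
  })
}

# Individuals ordered so that every parent precedes its children.
topological_order <- function(ped) {
  placed <- character(0)
  remaining <- ped
  out <- character(0)
  while (nrow(remaining)) {
    ready <- (is.na(remaining$father_id) | remaining$father_id %in% placed) &
      (is.na(remaining$mother_id) | remaining$mother_id %in% placed)
    if (!any(ready)) stop_format("pedigree has unresolvable parent links")
    out <- c(out, remaining$individual_id[ready])
    placed <- c(placed, remaining$individual_id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  out
}
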