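ped_status_codes <- c("0" = "unknown", "1" = "unaffected", "2" = "affected")

validate_pedigree <- function(ped) {
  # parental references must resolve within the family (or be NA), and no
  # individual may be its own ancestor
  for (fam in split(ped, ped$family_id)) {
    ids <- fam$individual_id
    if (anyDuplicated(ids)) {
      stop_format("duplicate individual id in family %s", fam$family_id[1])
    }
    for (col in c("father_id", "mother_id")) {
      ref <- fam[[col]]
      bad <- !is.na(ref) & !(ref %in% ids)
      if (any(bad)) {
        stop_format("parent %s of %s not found in family %s",
                    ref[bad][1], ids[bad][1], fam$family_id[1])
      }
    }
    parent_of <- function(id) {
      r <- fam[fam$individual_id == id, ]
      c(r$father_id, r$mother_id)
    }
    for (id in ids) {
      frontier <- setdiff(parent_of(id), NA)
      seen <- character(0)
      while (length(frontier)) {
        if (id %in% frontier) {
          stop_format("individual %s is its own ancestor in family %s",
                      id, fam$family_id[1])
        }
        seen <- union(seen, frontier)
        frontier <- setdiff(
          stats::na.omit(unlist(lapply(frontier, parent_of))), seen
        )
      }
    }
  }
  invisible(ped)
}

#' Read a 6-column PED pedigree file
#'
#' Whitespace-delimited pre-MAKEPED format: family id, individual id,
#' father id, mother id, sex (1 = male, 2 = female, 0 = unknown), phenotype
#' (1 = unaffected, 2 = affected, 0 = unknown). Parent id `"0"` means
#' missing. Self-ancestry, unresolved parent references and unknown status
#' codes are format errors.
#'
#' @param path Path to a PED file.
#' @param control_prefix Family-id prefix marking singleton population
#'   controls; matching families get `role = "population_control"`.
#' @return Tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `status`, `role`.
#' @export
read_ped <- function(path, control_prefix = "CTRL") {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(raw) != 6) {
    stop_format("PED file must have exactly 6 columns, found %d", ncol(raw))
  }
  names(raw) <- c("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "pheno")
  if (!all(raw$pheno %in% names(ped_status_codes))) {
    stop_format("unknown phenotype code(s): %s",
                paste(setdiff(raw$pheno, names(ped_status_codes)),
                      collapse = ", "))
  }
  if (!all(raw$sex %in% c("0", "1", "2"))) {
    stop_format("sex codes must be 0, 1 or 2")
  }
  ped <- tibble::tibble(
    family_id = raw$family_id,
    individual_id = raw$individual_id,
    father_id = dplyr::na_if(raw$father_id, "0"),
    mother_id = dplyr::na_if(raw$mother_id, "0"),
    sex = as.integer(raw$sex),
    status = unname(ped_status_codes[raw$pheno]),
    role = "family_member"
  )
  singleton <- ped$family_id %in%
    names(which(table(ped$family_id) == 1))
  ped$role[singleton & startsWith(ped$family_id, control_prefix)] <-
    "population_control"
  validate_pedigree(ped)
  ped
}

#' Write a pedigree tibble as a 6-column PED file
#'
#' @param ped Pedigree tibble as returned by [read_ped()] or
#'   [simulate_pedigrees()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  pheno <- names(ped_status_codes)[match(ped$status, ped_status_codes)]
  lines <- paste(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    ped$sex, pheno,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}
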