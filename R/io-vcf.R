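#' Variant table container
#'
#' Bundles a variant site tibble with its genotype dosage matrix. Built by
#' [read_vcf()] and by the cohort simulator.
#'
#' @param variants Tibble with columns `variant_key`, `chrom`, `pos`,
#'   `ref`, `alt` (plus optional extras such as `gene`).
#' @param genotypes Integer matrix of alternate-allele dosages in
#'   \{0, 1, 2, NA\}; rows named by `variant_key`, columns by individual id.
#' @param phased_gt Optional tibble `(variant_key, individual_id, gt)`
#'   retaining phased genotype strings where the source used `|`.
#' @return An object of class `fs_variants`.
#' @export
fs_variants <- function(variants, genotypes, phased_gt = NULL) {
  stopifnot(is.data.frame(variants), is.matrix(genotypes))
  if (anyDuplicated(variants$variant_key)) {
    stop_format("variant keys must be unique")
  }
  if (any(variants$pos < 1)) stop_format("positions must be >= 1")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop_format("dosages must be 0, 1, 2 or NA")
  rownames(genotypes) <- variants$variant_key
  structure(
    list(variants = tibble::as_tibble(variants), genotypes = genotypes,
         phased_gt = phased_gt),
    class = "fs_variants"
  )
}

#' @export
print.fs_variants <- function(x, ...) {
  cat(sprintf("<fs_variants> %d variants x %d individuals\n",
              nrow(x$variants), ncol(x$genotypes)))
  print(utils::head(x$variants, 5))
  invisible(x)
}

gt_to_dosage <- function(gt, alt_index) {
  # gt like "0/1", "1|2", "./.", ".", NA
  if (is.na(gt) || gt == "." || gt == "./." || gt == ".|.") return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles == as.character(alt_index))
}

#' Read a multi-sample VCF into a variant table
#'
#' Requires VCF v4.2-style input with a `#CHROM` header line and a GT
#' subfield. Multiallelic records are split into one biallelic row per
#' alternate allele (per-sample dosage = count of that allele), alleles are
#' normalised by trimming shared suffix then prefix sequence, `./.` becomes
#' missing, and phased separators `|` are accepted (phased genotype strings
#' are retained in `$phased_gt`). Rows are sorted by natural chromosome
#' order, position, then alleles.
#'
#' @param path Path to an uncompressed VCF file.
#' @return An [fs_variants] object.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (length(body) == 0 || !startsWith(body[1], "#CHROM")) {
    stop_format("VCF is missing the #CHROM header line")
  }
  n_col <- length(strsplit(body[1], "\t", fixed = TRUE)[[1]])
  if (n_col < 10) stop_format("VCF has no sample columns")
  widths <- lengths(strsplit(body[-1], "\t", fixed = TRUE))
  if (length(widths) && any(widths != n_col)) {
    stop_format("VCF sample count mismatch on data row(s) %s",
                paste(utils::head(which(widths != n_col), 3), collapse = ", "))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)

  rows <- list()
  phased <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- gt_raw[i, ]
    is_phased <- !is.na(gts) & grepl("|", gts, fixed = TRUE)
    for (j in seq_along(alts)) {
      norm <- normalize_alleles(as.integer(fix$POS[i]), fix$REF[i], alts[j])
      dos <- vapply(gts, gt_to_dosage, integer(1), alt_index = j)
      key <- variant_key(fix$CHROM[i], norm$pos, norm$ref, norm$alt)
      rows[[length(rows) + 1]] <- list(
        variant_key = key, chrom = fix$CHROM[i], pos = norm$pos,
        ref = norm$ref, alt = norm$alt, dosage = dos
      )
      if (any(is_phased)) {
        phased[[length(phased) + 1]] <- tibble::tibble(
          variant_key = key,
          individual_id = samples[is_phased],
          gt = unname(gts[is_phased])
        )
      }
    }
  }
  variants <- tibble::tibble(
    variant_key = vapply(rows, `[[`, character(1), "variant_key"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt")
  )
  genotypes <- do.call(rbind, lapply(rows, `[[`, "dosage"))
  colnames(genotypes) <- samples
  ord <- order(chrom_rank(variants$chrom), variants$pos,
               variants$ref, variants$alt)
  fs_variants(
    variants[ord, ], genotypes[ord, , drop = FALSE],
    phased_gt = if (length(phased)) dplyr::bind_rows(phased)
  )
}

#' Write a variant table as VCF v4.2
#'
#' Emits a minimal multi-sample VCF with only the GT subfield; dosage 0, 1,
#' 2, NA map to `0/0`, `0/1`, `1/1`, `./.`.
#'
#' @param x An [fs_variants] object (or cohort).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "fs_cohort")) x <- x$variant_table
  v <- x$variants
  g <- x$genotypes
  gt_str <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  gt_str[!is.na(g) & g == 0] <- "0/0"
  gt_str[!is.na(g) & g == 1] <- "0/1"
  gt_str[!is.na(g) & g == 2] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(g)), collapse = "\t")
  )
  body <- paste(
    v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
    apply(gt_str, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
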