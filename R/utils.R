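#' @importFrom rlang %||% .data
#' @importFrom stats rbinom rpois runif rnorm setNames
#' @importFrom utils head tail
NULL

# Natural chromosome order: chr1..chr22, chrX, chrY, then anything else
# alphabetically. Used everywhere a variant table is sorted so that
# variant_key order is stable across read order.
chrom_rank <- function(chrom) {
  core <- paste0("chr", c(1:22, "X", "Y", "M"))
  r <- match(chrom, core)
  extra <- sort(unique(chrom[is.na(r)]))
  r[is.na(r)] <- length(core) + match(chrom[is.na(r)], extra)
  r
}

#' Build a canonical variant key
#'
#' Keys have the form `chrom:pos:ref:alt` with 1-based positions, and are the
#' join handle between genotype, annotation and result tables.
#'
#' @param chrom Chromosome labels (e.g. `"chr1"`).
#' @param pos 1-based positions.
#' @param ref,alt Allele strings.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

sort_variants <- function(df) {
  df[order(chrom_rank(df$chrom), df$pos, df$ref, df$alt), , drop = FALSE]
}

# Left/right-trim shared allele sequence so that equivalent representations
# of the same biallelic event collapse to one key. Right (suffix) first,
# then left (prefix), always leaving at least one base on each allele.
normalize_alleles <- function(pos, ref, alt) {
  ref_c <- strsplit(ref, "")[[1]]
  alt_c <- strsplit(alt, "")[[1]]
  while (length(ref_c) > 1 && length(alt_c) > 1 &&
         ref_c[length(ref_c)] == alt_c[length(alt_c)]) {
    ref_c <- ref_c[-length(ref_c)]
    alt_c <- alt_c[-length(alt_c)]
  }
  while (length(ref_c) > 1 && length(alt_c) > 1 && ref_c[1] == alt_c[1]) {
    ref_c <- ref_c[-1]
    alt_c <- alt_c[-1]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(ref_c, collapse = ""),
       alt = paste(alt_c, collapse = ""))
}

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# All randomness in the package flows through seeds derived from one user
# seed; sub-seeds are deterministic functions of (seed, stream label).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h * 131) %% 2147483629L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
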