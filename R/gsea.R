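# Weighted Kolmogorov-Smirnov-style running-sum enrichment score, computed
# from hit positions only: between hits the running sum falls linearly, so
# its extrema occur immediately after a hit (maximum candidates) or
# immediately before one (minimum candidates), plus the terminal zero.
gsea_es <- function(hit_pos, abs_w, n_total) {
  k <- length(hit_pos)
  nr <- sum(abs_w)
  abs_w <- if (nr == 0) rep(1 / k, k) else abs_w / nr
  miss <- if (k == n_total) 0 else 1 / (n_total - k)
  cum <- cumsum(abs_w)
  v_after <- cum - (hit_pos - seq_len(k)) * miss
  v_before <- c(0, cum[-k]) - (hit_pos - seq_len(k)) * miss
  hi <- max(v_after)
  lo <- min(v_before, 0)
  if (hi >= abs(lo)) hi else lo
}

#' Preranked gene set enrichment analysis
#'
#' Genes are ranked by descending score (ties broken by gene symbol); for
#' each set a weighted running sum increments by `|score|^weight`
#' (normalised by the in-set total) at member genes and decrements by
#' `1/(N - N_set)` elsewhere. The enrichment score (ES) is the maximum
#' signed deviation of this sum. The null distribution comes from `n_perm`
#' random gene sets of the same size drawn without replacement (cached per
#' set size within a call, so same-size sets share one null);
#' `p_nominal = (1 + #{|ES_perm| >= |ES|}) / (1 + n_perm)`,
#' `NES = ES / mean(|ES_perm|)`, and FDR q-values are Benjamini-Hochberg
#' across sets. The leading edge lists the member genes at or before the
#' ES peak (at or after it for depletion-signed scores).
#'
#' @param ranking Named numeric vector of gene scores, or a two-column
#'   data frame `(gene, score)`. Missing scores are an error.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param weight Exponent on `|score|` for hit increments (default 1,
#'   the standard weighted statistic).
#' @param n_perm Number of null permutations.
#' @param seed Integer seed for the permutation null.
#' @return Object of class `fs_gsea`: tibble `(set, size, es, nes,
#'   p_nominal, fdr_q, leading_edge)` sorted by `p_nominal`, with
#'   parameters stored as attributes. Sets with no gene in the universe
#'   are skipped with a warning.
#' @export
gsea_preranked <- function(ranking, sets, weight = 1, n_perm = 1000,
                           seed = 1) {
  if (is.data.frame(ranking)) {
    ranking <- setNames(ranking[[2]], ranking[[1]])
  }
  if (any(is.na(ranking))) stop_format("ranking has missing scores")
  ord <- order(-ranking, names(ranking))
  scores <- ranking[ord]
  genes <- names(scores)
  n_total <- length(genes)
  abs_w_all <- abs(scores)^weight

  empty <- vapply(sets, function(s) length(intersect(s, genes)) == 0,
                  logical(1))
  if (any(empty)) {
    warning(sprintf("skipping %d set(s) with no gene in the universe: %s",
                    sum(empty), paste(names(sets)[empty], collapse = ", ")),
            call. = FALSE)
    sets <- sets[!empty]
  }
  if (length(sets) == 0) {
    stop_format("no gene set intersects the ranking universe")
  }

  observed <- purrr::map(sets, function(s) {
    hit_pos <- sort(match(intersect(s, genes), genes))
    es <- gsea_es(hit_pos, abs_w_all[hit_pos], n_total)
    # leading edge: members at/before the positive peak, at/after the dip
    k <- length(hit_pos)
    nr <- sum(abs_w_all[hit_pos])
    w <- if (nr == 0) rep(1 / k, k) else abs_w_all[hit_pos] / nr
    miss <- if (k == n_total) 0 else 1 / (n_total - k)
    cum <- cumsum(w)
    v_after <- cum - (hit_pos - seq_len(k)) * miss
    v_before <- c(0, cum[-k]) - (hit_pos - seq_len(k)) * miss
    le <- if (es >= 0) {
      genes[hit_pos[seq_len(which.max(v_after))]]
    } else {
      genes[hit_pos[seq(which.min(v_before), k)]]
    }
    list(size = k, es = es, leading_edge = le)
  })

  sizes <- vapply(observed, `[[`, integer(1), "size")
  null_by_size <- list()
  with_seed(derive_seed(seed, "gsea"), {
    for (k in sort(unique(sizes))) {
      null_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
        pos <- sort(sample.int(n_total, k))
        gsea_es(pos, abs_w_all[pos], n_total)
      }, numeric(1))
    }
  })

  res <- tibble::tibble(
    set = names(observed),
    size = unname(sizes),
    es = unname(vapply(observed, `[[`, numeric(1), "es")),
    leading_edge = purrr::map(observed, "leading_edge")
  )
  res <- dplyr::mutate(
    res,
    nes = purrr::map2_dbl(.data$es, .data$size, function(e, k) {
      e / mean(abs(null_by_size[[as.character(k)]]))
    }),
    p_nominal = purrr::map2_dbl(.data$es, .data$size, function(e, k) {
      (1 + sum(abs(null_by_size[[as.character(k)]]) >= abs(e))) / (1 + n_perm)
    }),
    fdr_q = bh_fdr(.data$p_nominal)
  )
  res <- dplyr::arrange(res, .data$p_nominal, .data$set)
  res <- res[, c("set", "size", "es", "nes", "p_nominal", "fdr_q",
                 "leading_edge")]
  structure(res, weight = weight, n_perm = n_perm, seed = seed,
            class = c("fs_gsea", class(res)))
}
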