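# Self-implemented statistical primitives for the downstream stages.
# Each is deliberately written from the defining formula (hypergeometric
# tail sums, rank-split enumeration, closed-form 2x2 chi-square, BH step-up)
# and is cross-checked against independent oracles in the test suite.

log_sum_exp <- function(lx) {
  if (length(lx) == 0) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

check_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop_format("2x2 table cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop_format("2x2 table must have a positive total")
  invisible(cells)
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional test with both margins fixed: the p-value is the
#' hypergeometric tail sum over tables at least as extreme as the observed
#' one. Cells are laid out as rows = case/control, columns =
#' carrier/non-carrier, so `a` is the case-carrier cell and
#' `tail = "greater"` asks for an excess of case carriers.
#'
#' Tail sums are accumulated in log space, so p-values below the smallest
#' normalised double are returned as tiny positive numbers rather than 0.
#'
#' @param a,b,c,d Cell counts: `a` case carriers, `b` case non-carriers,
#'   `c` control carriers, `d` control non-carriers.
#' @param tail One of `"greater"`, `"less"`, `"two_sided"`. `"greater"` sums
#'   over tables with the `a` cell at or above the observed value;
#'   `"two_sided"` sums the probabilities of all tables no more probable
#'   than the observed one.
#' @return A single p-value in (0, 1].
#' @examples
#' fisher_exact(3, 103, 0, 193, tail = "greater")
#' @export
fisher_exact <- function(a, b, c, d, tail = c("greater", "less", "two_sided")) {
  tail <- match.arg(tail)
  check_2x2(a, b, c, d)
  r1 <- a + b
  r2 <- c + d
  k <- a + c # carrier margin
  n <- r1 + r2
  lo <- max(0L, k - r2)
  hi <- min(r1, k)
  x <- lo:hi
  # log P(X = x) for X ~ Hypergeom(n, r1, k)
  lp <- lchoose(r1, x) + lchoose(r2, k - x) - lchoose(n, k)
  lp_obs <- lp[x == a]
  lp_val <- switch(tail,
    greater = log_sum_exp(lp[x >= a]),
    less = log_sum_exp(lp[x <= a]),
    two_sided = log_sum_exp(lp[lp <= lp_obs + 1e-07])
  )
  min(exp(lp_val), 1)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Uses midranks for ties. In `"exact"` mode the null distribution of the U
#' statistic is built by enumerating all `choose(n + m, n)` assignments of
#' the pooled ranks to the first sample (guarded to `n + m <= 16`); in
#' `"normal_approx"` mode a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"exact"` or `"normal_approx"`.
#' @param alternative `"two_sided"` (default), `"greater"` (x tends larger),
#'   or `"less"`.
#' @return List with elements `statistic` (U for the first sample) and
#'   `p.value`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("normal_approx", "exact"),
                              alternative = c("two_sided", "greater", "less")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    stop_format("both samples must be non-empty")
  }
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled) # midranks
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (mode == "exact") {
    if (n + m > 16) {
      stop_format(paste(
        "exact mode is limited to n + m <= 16;",
        "use mode = 'normal_approx' for larger samples"
      ))
    }
    splits <- utils::combn(n + m, n)
    u_null <- colSums(matrix(r[splits], nrow = n)) - n * (n + 1) / 2
    mu <- n * m / 2
    p <- switch(alternative,
      two_sided = mean(abs(u_null - mu) >= abs(u_obs - mu) - 1e-09),
      greater = mean(u_null >= u_obs - 1e-09),
      less = mean(u_null <= u_obs + 1e-09)
    )
  } else {
    mu <- n * m / 2
    nn <- n + m
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    v <- n * m / 12 * ((nn + 1) - tie_term)
    if (v <= 0) {
      # all observations identical: no evidence either way
      return(list(statistic = u_obs, p.value = 1))
    }
    cc <- 0.5
    p <- switch(alternative,
      two_sided = {
        z <- (abs(u_obs - mu) - cc) / sqrt(v)
        min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
      },
      greater = stats::pnorm((u_obs - mu - cc) / sqrt(v), lower.tail = FALSE),
      less = stats::pnorm((u_obs - mu + cc) / sqrt(v))
    )
  }
  list(statistic = u_obs, p.value = min(max(p, 0), 1))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed form without continuity correction:
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, referred to a chi-square
#' distribution with one degree of freedom. All four margins must be
#' positive.
#'
#' @inheritParams fisher_exact
#' @return List with `statistic` and `p.value`.
#' @examples
#' chi_square_2x2(20, 80, 10, 90)
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  check_2x2(a, b, c, d)
  if (min(a + b, c + d, a + c, b + d) == 0) {
    stop_format("chi-square requires all four margins to be positive")
  }
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up procedure: `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1,
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_format("p-values must lie in [0, 1]")
  }
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}
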