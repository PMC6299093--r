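# One-sample Wilcoxon signed-rank test, the per-window test of the
# enrichment profile. Zero differences are dropped (standard convention);
# the exact null distribution is used for n <= 25 when the absolute
# differences are tie-free, otherwise the normal approximation with
# continuity correction.

#' One-sample Wilcoxon signed-rank test against mu
#'
#' Thin, convention-pinning wrapper around [stats::wilcox.test()]: zeros
#' are dropped before ranking, the exact distribution is used for
#' `n <= exact_max` untied samples, and larger (or tied) samples use the
#' normal approximation with continuity correction. For `n = 5` all-positive
#' values the two-sided exact p is 2/2^5 = 0.0625.
#'
#' @param x Numeric sample.
#' @param mu Null location (default 0).
#' @param exact_max Largest n for the exact branch (default 25).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List: `statistic` (V, sum of positive ranks), `p.value`,
#'   `n_used` (after zero removal), `n_zero`, `exact` (logical), `method`.
#'   With no nonzero differences the test is withheld: `p.value = NA`.
#' @export
signed_rank_test <- function(x, mu = 0, exact_max = 25,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x[!is.na(x)] - mu
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p.value = NA_real_, n_used = 0L,
                n_zero = n_zero, exact = NA,
                method = "withheld (no nonzero differences)"))
  }
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- n <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  list(
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    n_used = n,
    n_zero = n_zero,
    exact = exact,
    method = if (exact) "exact signed-rank" else
      "signed-rank, normal approximation with continuity correction"
  )
}
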