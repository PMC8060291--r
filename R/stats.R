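#' Fisher's exact test for tissue-specific enrichment
#'
#' Tests whether tissue-specific genes are over-represented among the called
#' biomarkers relative to the annotated genome, via Fisher's exact test on
#' the 2x2 table of (biomarker vs rest) by (tissue-specific vs not).
#'
#' @param n_dcb_specific Biomarkers that are tissue-specific (a).
#' @param n_dcb Total biomarkers called.
#' @param n_specific_genome Tissue-specific genes in the annotated genome.
#' @param n_genome Annotated genes in total.
#'
#' @return One-row tibble: `odds_ratio` (conditional MLE), `p_value`
#'   (two-sided).
#' @export
#' @examples
#' fisher_enrichment(6, 12, 173, 57820)
fisher_enrichment <- function(n_dcb_specific, n_dcb, n_specific_genome, n_genome) {
  a <- n_dcb_specific
  b <- n_dcb - a
  cc <- n_specific_genome - a
  d <- n_genome - n_dcb - n_specific_genome + a
  if (any(c(a, b, cc, d) < 0) || n_dcb > n_genome || n_specific_genome > n_genome) {
    abort("inconsistent margins: counts must satisfy a <= n_dcb <= n_genome and a <= n_specific_genome <= n_genome.")
  }
  ft <- fisher.test(matrix(c(a, cc, b, d), nrow = 2))
  tibble::tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Two-sided rank-sum (Mann-Whitney U) test
#'
#' Compares two groups of values by the Wilcoxon rank-sum statistic. For
#' small problems (combined n <= `exact_limit`) the two-sided p-value is
#' computed by exhaustive enumeration of all group assignments over the
#' (tie-aware, midrank) pooled ranks -- exact even in the presence of ties.
#' Larger problems use the normal approximation with tie correction and
#' continuity correction ([stats::wilcox.test()]).
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @param exact_limit Combined-size threshold for the exact branch
#'   (default 12).
#'
#' @return One-row tibble: `statistic` (U for the first group), `p_value`,
#'   `method` ("exact" or "normal approximation").
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))
rank_sum_test <- function(values_a, values_b, exact_limit = 12) {
  if (!length(values_a) || !length(values_b)) {
    abort("both groups must be non-empty.")
  }
  na <- length(values_a)
  nb <- length(values_b)
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2

  if (na + nb <= exact_limit) {
    combos <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    center <- na * nb / 2
    p <- mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
    return(tibble::tibble(statistic = u_obs, p_value = p, method = "exact"))
  }
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)
  )
  tibble::tibble(statistic = u_obs, p_value = wt$p.value,
                 method = "normal approximation")
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Standard step-up procedure: adjusted p-values via
#' [stats::p.adjust()]`(method = "BH")`, with genes rejected at FDR level
#' `q` when their adjusted p-value is at most `q`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   carried through unrejected).
#' @param q FDR level (default 0.05).
#'
#' @return Tibble with `p_value`, `p_adjusted`, `rejected`, in input order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03), q = 0.05)
benjamini_hochberg <- function(pvalues, q = 0.05) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  if (q <= 0 || q > 1) abort("`q` must lie in (0, 1].")
  adj <- p.adjust(pvalues, method = "BH")
  tibble::tibble(
    p_value = pvalues,
    p_adjusted = adj,
    rejected = !is.na(adj) & adj <= q
  )
}
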