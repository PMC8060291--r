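#' Bimodal false-positive filter
#'
#' Flags a gene whose expression is bimodal in \emph{both} the non-cancer and
#' the cancer group. Bimodality in both groups indicates population
#' heterogeneity unrelated to cancer (e.g. an eQTL), which violates the NB
#' assumption of the GLM and produces spuriously small p-values. Bimodality
#' in the cancer group alone -- a genuine subtype-specific biomarker pattern
#' -- is \emph{not} flagged.
#'
#' @param values Per-sample expression of one gene, in RPM.
#' @param group `"noncancer"`/`"cancer"` label per sample (>= 6 per group).
#' @param lambda_max,seed Passed to [fit_poisson_normal_mixture()].
#'
#' @return One-row tibble: `bimodal_flag`, `pi1_noncancer`, `pi1_cancer`.
#' @export
bimodal_fp_filter <- function(values, group, lambda_max = 1, seed = 1L) {
  group <- as.character(group)
  bad <- setdiff(unique(group), c("noncancer", "cancer"))
  if (length(bad)) abort("`group` must be 'noncancer' or 'cancer'.")
  vals_nc <- values[group == "noncancer"]
  vals_ca <- values[group == "cancer"]
  if (length(vals_nc) < 6L || length(vals_ca) < 6L) {
    abort("both groups need at least 6 samples for the bimodality filter.")
  }
  fit_nc <- fit_poisson_normal_mixture(vals_nc, lambda_max = lambda_max, seed = seed)
  fit_ca <- fit_poisson_normal_mixture(vals_ca, lambda_max = lambda_max, seed = seed)
  tibble::tibble(
    bimodal_flag = is_bimodal(fit_nc) && is_bimodal(fit_ca),
    pi1_noncancer = fit_nc$pi1,
    pi1_cancer = fit_ca$pi1
  )
}

#' Influential-outlier false-positive filter (Cook's distance refit)
#'
#' Checks whether a single influential sample is responsible for a
#' significant NB-GLM fit: computes per-sample Cook's distances (see
#' [cooks_distance_nbglm()]), refits the model without the sample with the
#' largest distance, and flags the gene when the refitted p-value is no
#' longer significant at `alpha_cut`. A refit that fails to converge (or is
#' degenerate, e.g. all remaining counts zero) is flagged, conservatively.
#'
#' @param fit A converged, significant `nbglm` fit from [fit_nbglm()].
#' @param alpha_cut Significance cut-off used for the original call
#'   (default 0.05).
#'
#' @return One-row tibble: `outlier_flag`, `dropped_index`, `max_cooks`,
#'   `refit_p_value`.
#' @export
cooks_outlier_filter <- function(fit, alpha_cut = 0.05) {
  stopifnot(inherits(fit, "nbglm"))
  if (!fit$converged || is.na(fit$p_value)) {
    abort("the outlier filter requires a converged fit with a p-value.")
  }
  n <- length(fit$y)
  if (n < 5L) abort("at least 5 samples are required for the refit.")
  d <- cooks_distance_nbglm(fit)
  drop <- which.max(d)
  keep <- setdiff(seq_len(n), drop)
  refit <- tryCatch(
    fit_nbglm(fit$y[keep], fit$covariate[keep], offset = fit$offset[keep]),
    error = function(e) NULL
  )
  refit_p <- if (!is.null(refit) && refit$converged) refit$p_value else NA_real_
  flag <- is.na(refit_p) || refit_p >= alpha_cut
  if (is.na(refit_p)) {
    warn("refit without the most influential sample did not converge; flagged conservatively.")
  }
  tibble::tibble(
    outlier_flag = flag,
    dropped_index = drop,
    max_cooks = d[drop],
    refit_p_value = refit_p
  )
}
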