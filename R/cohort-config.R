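#' Configuration for a synthetic cfRNA cohort
#'
#' Builds the parameter set consumed by [simulate_cohort()]. Defaults emulate
#' the discovery-cohort design the package targets: 93 non-cancer and 79
#' cancer plasma samples, ~2000 genes with a small number of planted
#' dark-channel biomarkers (DCBs) and false-positive genes, heavy-tailed
#' per-sample sequencing depth (log-normal, CV 0.83), and cfDNA tumor
#' fractions spanning roughly 0.1--10%.
#'
#' Gene classes generated:
#' \describe{
#'   \item{background}{negative-binomial counts in all samples, mean scaled by
#'     per-sample depth.}
#'   \item{dark}{zero counts everywhere (dark channels with no cancer signal).}
#'   \item{dcb}{zero in every non-cancer sample; in cancer sample \eqn{j} the
#'     NB mean is \eqn{tf_j \times e_{gj} \times depth_j / 10^6}, i.e. plasma
#'     abundance proportional to tumor content (tumor fraction times
#'     matched-tumor expression).}
#'   \item{bimodal_fp}{a two-component mixture in \emph{both} groups:
#'     with probability `bimodal_mix_weight` a near-zero Poisson draw,
#'     otherwise an NB draw with high mean -- the failure mode the heteroDE
#'     bimodality filter is built to catch.}
#'   \item{outlier_fp}{zero everywhere except one cancer sample carrying a
#'     single large count (`outlier_magnitude` times the 99th percentile of
#'     background counts) -- the failure mode the Cook's-distance refit
#'     catches.}
#' }
#'
#' @param n_noncancer,n_cancer Number of samples per group.
#' @param n_background_genes,n_dark_genes,n_dcb_genes,n_bimodal_fp_genes,n_outlier_fp_genes
#'   Gene counts per class.
#' @param depth_mean Mean library size (collapsed strict mapped reads).
#' @param depth_cv Coefficient of variation of library size (log-normal).
#' @param background_log_mean_range Interval of per-gene background mean
#'   expression, in log10 RPM. Background genes model the reliably expressed
#'   blood-cell-derived background (default 2--30 RPM); genes below the
#'   detection threshold belong to the `dark` class, so each simulated gene
#'   has a well-defined class.
#' @param dispersion_range Interval for the NB dispersion \eqn{\alpha}
#'   (variance \eqn{m + \alpha m^2}).
#' @param tumor_fraction_range Interval in (0, 1); tumor fractions are drawn
#'   log-uniformly within it.
#' @param dcb_tissue_expr_range RPM interval for DCB-gene expression in the
#'   simulated matched tumor tissue.
#' @param bimodal_zero_lambda,bimodal_high_mean,bimodal_high_dispersion,bimodal_mix_weight
#'   Parameters of the bimodal false-positive mixture.
#' @param outlier_magnitude Multiple of the background 99th-percentile count
#'   given to the single outlier sample.
#' @param n_tissues,signature_genes_per_tissue Size of the synthetic tissue
#'   median-expression reference generated alongside the cohort.
#' @param seed Integer RNG seed; fixing it fixes every output bit.
#'
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_noncancer = 10, n_cancer = 8, seed = 7)
#' cfg$n_dcb_genes
cohort_config <- function(n_noncancer = 93L,
                          n_cancer = 79L,
                          n_background_genes = 1920L,
                          n_dark_genes = 60L,
                          n_dcb_genes = 10L,
                          n_bimodal_fp_genes = 5L,
                          n_outlier_fp_genes = 5L,
                          depth_mean = 3e6,
                          depth_cv = 0.83,
                          background_log_mean_range = c(0.3, 1.5),
                          dispersion_range = c(0.1, 0.6),
                          tumor_fraction_range = c(0.001, 0.1),
                          dcb_tissue_expr_range = c(50, 500),
                          bimodal_zero_lambda = 0.1,
                          bimodal_high_mean = 50,
                          bimodal_high_dispersion = 0.2,
                          bimodal_mix_weight = 0.5,
                          outlier_magnitude = 20,
                          n_tissues = 5L,
                          signature_genes_per_tissue = 25L,
                          seed = 1L) {
  cfg <- list(
    n_noncancer = as.integer(n_noncancer),
    n_cancer = as.integer(n_cancer),
    n_background_genes = as.integer(n_background_genes),
    n_dark_genes = as.integer(n_dark_genes),
    n_dcb_genes = as.integer(n_dcb_genes),
    n_bimodal_fp_genes = as.integer(n_bimodal_fp_genes),
    n_outlier_fp_genes = as.integer(n_outlier_fp_genes),
    depth_mean = depth_mean,
    depth_cv = depth_cv,
    background_log_mean_range = background_log_mean_range,
    dispersion_range = dispersion_range,
    tumor_fraction_range = tumor_fraction_range,
    dcb_tissue_expr_range = dcb_tissue_expr_range,
    bimodal_zero_lambda = bimodal_zero_lambda,
    bimodal_high_mean = bimodal_high_mean,
    bimodal_high_dispersion = bimodal_high_dispersion,
    bimodal_mix_weight = bimodal_mix_weight,
    outlier_magnitude = outlier_magnitude,
    n_tissues = as.integer(n_tissues),
    signature_genes_per_tissue = as.integer(signature_genes_per_tissue),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  counts <- c(
    "n_noncancer", "n_cancer", "n_background_genes", "n_dark_genes",
    "n_dcb_genes", "n_bimodal_fp_genes", "n_outlier_fp_genes",
    "n_tissues", "signature_genes_per_tissue"
  )
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 0L) {
      abort(sprintf("`%s` must be a single non-negative integer.", nm))
    }
  }
  if (cfg$n_noncancer < 1L || cfg$n_cancer < 1L) {
    abort("both sample groups must contain at least one sample.")
  }
  for (nm in c("background_log_mean_range", "dispersion_range",
               "tumor_fraction_range", "dcb_tissue_expr_range")) {
    iv <- cfg[[nm]]
    if (length(iv) != 2L || any(!is.finite(iv)) || iv[1] > iv[2]) {
      abort(sprintf("`%s` must be a finite interval c(lower, upper) with lower <= upper.", nm))
    }
  }
  tf <- cfg$tumor_fraction_range
  if (tf[1] <= 0 || tf[2] >= 1) abort("`tumor_fraction_range` must lie strictly inside (0, 1).")
  if (cfg$depth_mean <= 0 || cfg$depth_cv < 0) abort("`depth_mean` must be > 0 and `depth_cv` >= 0.")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  samples: %d noncancer + %d cancer\n", x$n_noncancer, x$n_cancer))
  cat(sprintf(
    "  genes:   %d background, %d dark, %d dcb, %d bimodal-FP, %d outlier-FP\n",
    x$n_background_genes, x$n_dark_genes, x$n_dcb_genes,
    x$n_bimodal_fp_genes, x$n_outlier_fp_genes
  ))
  cat(sprintf("  depth:   lognormal(mean %.3g, cv %.2f); seed %d\n",
              x$depth_mean, x$depth_cv, x$seed))
  invisible(x)
}
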