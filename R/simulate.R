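#' Simulate a cfRNA cohort with ground truth
#'
#' Generates a genes-by-samples strict-count matrix with the statistical
#' structure the downstream pipeline assumes (see [cohort_config()] for the
#' generative model of each gene class), together with sample metadata, a
#' ground-truth object, and a synthetic tissue median-expression reference for
#' deconvolution. Output is byte-identical for a fixed seed.
#'
#' @param config A [cohort_config()] object.
#'
#' @return A list of class `synthetic_cohort` with elements
#' \describe{
#'   \item{counts}{tibble, `gene` column plus one integer column per sample.}
#'   \item{metadata}{tibble: sample_id, group, cancer_type, subtype,
#'     tumor_fraction, total_counts.}
#'   \item{truth}{list with `gene_class`, `dcb_tissue`, `tumor_fraction`,
#'     `tissue_expression` (matched-tumor RPM per gene and cancer sample) and
#'     `mixture_fractions` (per-sample tissue fractions, sum <= 1).}
#'   \item{tissue_reference}{tibble of median expression, genes in rows,
#'     one column per tissue (GTEx-style).}
#' }
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_noncancer = 12, n_cancer = 10,
#'   n_background_genes = 50, n_dark_genes = 5, seed = 1))
#' dplyr::count(cohort$truth$gene_class, class)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  withr::local_seed(config$seed)

  n_nc <- config$n_noncancer
  n_ca <- config$n_cancer
  n_samples <- n_nc + n_ca
  sample_id <- c(sprintf("NC%03d", seq_len(n_nc)), sprintf("Ca%03d", seq_len(n_ca)))
  group <- rep(c("noncancer", "cancer"), c(n_nc, n_ca))

  # roughly 60/40 breast/lung split among cancers, as in a mixed cohort
  n_breast <- max(1L, round(0.6 * n_ca))
  cancer_type <- c(rep(NA_character_, n_nc),
                   rep(c("breast", "lung"), c(n_breast, n_ca - n_breast)))
  subtype <- rep(NA_character_, n_samples)
  is_breast <- !is.na(cancer_type) & cancer_type == "breast"
  is_lung <- !is.na(cancer_type) & cancer_type == "lung"
  subtype[is_breast] <- sample(c("HR+", "TNBC"), sum(is_breast), replace = TRUE, prob = c(0.6, 0.4))
  subtype[is_lung] <- sample(c("adenocarcinoma", "squamous"), sum(is_lung), replace = TRUE)

  # library sizes: log-normal with the requested mean and CV
  sdlog <- sqrt(log(1 + config$depth_cv^2))
  meanlog <- log(config$depth_mean) - sdlog^2 / 2
  totals <- pmax(1, round(rlnorm(n_samples, meanlog, sdlog)))
  depth_scale <- totals / 1e6 # counts per RPM

  # tumor fractions, log-uniform over the configured range
  tf_range <- config$tumor_fraction_range
  tumor_fraction <- rep(NA_real_, n_samples)
  tumor_fraction[group == "cancer"] <-
    10^runif(n_ca, log10(tf_range[1]), log10(tf_range[2]))

  gene_ids <- function(prefix, n) if (n > 0) sprintf("%s%04d", prefix, seq_len(n)) else character()
  genes_bg <- gene_ids("BG", config$n_background_genes)
  genes_dark <- gene_ids("DARK", config$n_dark_genes)
  genes_dcb <- gene_ids("DCB", config$n_dcb_genes)
  genes_bfp <- gene_ids("BFP", config$n_bimodal_fp_genes)
  genes_ofp <- gene_ids("OFP", config$n_outlier_fp_genes)
  genes <- c(genes_bg, genes_dark, genes_dcb, genes_bfp, genes_ofp)
  if (!length(genes)) abort("configuration generates zero genes.")

  counts <- matrix(0L, nrow = length(genes), ncol = n_samples,
                   dimnames = list(genes, sample_id))

  rnb <- function(n, mu, alpha) {
    # NB with variance mu + alpha * mu^2; Poisson limit at alpha ~ 0
    if (alpha < 1e-12) rpois(n, mu) else rnbinom(n, size = 1 / alpha, mu = mu)
  }

  # background genes
  if (length(genes_bg)) {
    log_mu <- runif(length(genes_bg), config$background_log_mean_range[1],
                    config$background_log_mean_range[2])
    alpha_bg <- runif(length(genes_bg), config$dispersion_range[1], config$dispersion_range[2])
    for (i in seq_along(genes_bg)) {
      mu <- 10^log_mu[i] * depth_scale
      counts[genes_bg[i], ] <- rnb(n_samples, mu, alpha_bg[i])
    }
  }

  # dcb genes: silent in non-cancer, tumor-content-driven in cancer
  tissues <- sprintf("T%02d", seq_len(max(config$n_tissues, 1L)))
  dcb_tissue <- character(0)
  tissue_expr <- NULL
  if (length(genes_dcb)) {
    dcb_tissue <- tissues[((seq_along(genes_dcb) - 1L) %% length(tissues)) + 1L]
    alpha_dcb <- runif(length(genes_dcb), config$dispersion_range[1], config$dispersion_range[2])
    ca_idx <- which(group == "cancer")
    e <- matrix(runif(length(genes_dcb) * n_ca,
                      config$dcb_tissue_expr_range[1], config$dcb_tissue_expr_range[2]),
                nrow = length(genes_dcb),
                dimnames = list(genes_dcb, sample_id[ca_idx]))
    for (i in seq_along(genes_dcb)) {
      mu <- tumor_fraction[ca_idx] * e[i, ] * depth_scale[ca_idx]
      counts[genes_dcb[i], ca_idx] <- rnb(n_ca, mu, alpha_dcb[i])
    }
    tissue_expr <- e
  }

  # bimodal false positives: two-component mixture in both groups
  if (length(genes_bfp)) {
    for (g in genes_bfp) {
      z <- rbinom(n_samples, 1L, config$bimodal_mix_weight)
      high <- rnb(n_samples, config$bimodal_high_mean * totals / config$depth_mean,
                  config$bimodal_high_dispersion)
      counts[g, ] <- ifelse(z == 1L, rpois(n_samples, config$bimodal_zero_lambda), high)
    }
  }

  # matched-tumor expression for non-dcb genes: modest background expression
  ca_samples <- sample_id[group == "cancer"]
  other_genes <- setdiff(genes, genes_dcb)
  expr_other <- matrix(runif(length(other_genes) * n_ca, 1, 20),
                       nrow = length(other_genes),
                       dimnames = list(other_genes, ca_samples))

  # outlier false positives: one large count in a single random cancer
  # sample -- the single-influential-outlier failure mode that inflates the
  # GLM slope and that the Cook's-distance refit is built to catch
  if (length(genes_ofp)) {
    bg_counts <- if (length(genes_bg)) counts[genes_bg, , drop = FALSE] else counts
    q99 <- quantile(as.numeric(bg_counts), 0.99, names = FALSE)
    for (g in genes_ofp) {
      target <- ca_samples[sample.int(n_ca, 1L)]
      counts[g, target] <- max(1, round(config$outlier_magnitude * q99))
    }
  }

  storage.mode(counts) <- "integer"
  expr_all <- rbind(if (!is.null(tissue_expr)) tissue_expr else NULL, expr_other)
  expr_all <- expr_all[intersect(genes, rownames(expr_all)), , drop = FALSE]
  tissue_expression <- tibble::as_tibble(expr_all, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "tissue_expression_rpm")

  # per-sample tissue mixture fractions on the simplex (sum <= 1; the
  # remainder models unprofiled tissues)
  gm <- matrix(rgamma(n_samples * (length(tissues) + 1L), shape = 1), nrow = n_samples)
  fr <- gm / rowSums(gm)
  mixture_fractions <- tibble::tibble(
    sample_id = rep(sample_id, each = length(tissues)),
    tissue = rep(tissues, times = n_samples),
    fraction = as.vector(t(fr[, seq_along(tissues), drop = FALSE]))
  )

  tissue_reference <- simulate_tissue_reference(
    tissues, config$signature_genes_per_tissue
  )

  metadata <- tibble::tibble(
    sample_id = sample_id, group = group, cancer_type = cancer_type,
    subtype = subtype, tumor_fraction = tumor_fraction,
    total_counts = as.numeric(totals)
  )

  truth <- list(
    gene_class = tibble::tibble(
      gene = genes,
      class = rep(c("background", "dark", "dcb", "bimodal_fp", "outlier_fp"),
                  c(length(genes_bg), length(genes_dark), length(genes_dcb),
                    length(genes_bfp), length(genes_ofp)))
    ),
    dcb_tissue = tibble::tibble(gene = genes_dcb, tissue = dcb_tissue),
    tumor_fraction = tibble::tibble(sample_id = ca_samples,
                                    tumor_fraction = tumor_fraction[group == "cancer"]),
    tissue_expression = tissue_expression,
    mixture_fractions = mixture_fractions
  )

  structure(
    list(counts = gene_matrix_to_tibble(counts), metadata = metadata,
         truth = truth, tissue_reference = tissue_reference),
    class = "synthetic_cohort"
  )
}

# Tissue median-expression reference: each tissue gets a block of candidate
# genes strongly expressed in that tissue and near-silent elsewhere.
simulate_tissue_reference <- function(tissues, genes_per_tissue) {
  p <- length(tissues)
  n_genes <- p * genes_per_tissue
  if (n_genes == 0L) {
    return(tibble::tibble(gene = character()))
  }
  gene <- sprintf("SIG_%s_%02d", rep(tissues, each = genes_per_tissue),
                  rep(seq_len(genes_per_tissue), times = p))
  X <- matrix(runif(n_genes * p, 0, 0.5), nrow = n_genes,
              dimnames = list(gene, tissues))
  for (i in seq_len(p)) {
    rows <- (i - 1L) * genes_per_tissue + seq_len(genes_per_tissue)
    X[rows, i] <- runif(genes_per_tissue, 30, 300)
  }
  tibble::as_tibble(X, rownames = "gene")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d genes x %d samples (%d noncancer, %d cancer)\n",
              nrow(x$counts), ncol(x$counts) - 1L,
              sum(x$metadata$group == "noncancer"),
              sum(x$metadata$group == "cancer")))
  print(dplyr::count(x$truth$gene_class, .data$class))
  invisible(x)
}

#' Simulate a cfRNA expression vector as a tissue mixture
#'
#' Draws `y = X beta + eps` over the signature genes: the linear mixing model
#' the deconvolution stage inverts. Gaussian noise is truncated at zero since
#' expression is non-negative.
#'
#' @param signature A `tissue_signature` from [select_signature_genes()].
#' @param fractions Non-negative tissue-fraction vector of length
#'   `length(signature$tissues)`, summing to at most 1.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in RPM.
#'
#' @return Tibble with columns `gene` and `rpm`.
#' @export
simulate_tissue_mixture <- function(signature, fractions, noise_sd = 0) {
  stopifnot(inherits(signature, "tissue_signature"))
  p <- length(signature$tissues)
  if (length(fractions) != p) {
    abort(sprintf("`fractions` has length %d but the signature has %d tissues.",
                  length(fractions), p))
  }
  if (any(fractions < 0) || sum(fractions) > 1 + 1e-9) {
    abort("`fractions` must be non-negative and sum to at most 1.")
  }
  if (!nrow(signature$X)) abort("signature has no genes.")
  y <- as.vector(signature$X %*% fractions)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  tibble::tibble(gene = rownames(signature$X), rpm = pmax(y, 0))
}
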