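# Shared fixtures: cohorts are always generated in code, never stored.

# The strong-effect condition used for truth-recovery checks: high-shedding
# tumors with highly expressed markers in matched tissue.
strong_config <- function(seed, n_noncancer = 40L, n_cancer = 40L, ...) {
  cohort_config(
    n_noncancer = n_noncancer, n_cancer = n_cancer,
    tumor_fraction_range = c(0.02, 0.1),
    dcb_tissue_expr_range = c(100, 500),
    seed = seed, ...
  )
}

strong_cohort <- function(seed, ...) simulate_cohort(strong_config(seed, ...))

# A small, fast cohort for structural tests.
tiny_cohort <- function(seed = 1L) {
  simulate_cohort(cohort_config(
    n_noncancer = 12L, n_cancer = 10L, n_background_genes = 40L,
    n_dark_genes = 6L, n_dcb_genes = 3L, n_bimodal_fp_genes = 2L,
    n_outlier_fp_genes = 2L, seed = seed
  ))
}

tbl_to_matrix <- function(tbl) {
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl[[1]]
  m
}

genes_of_class <- function(cohort, cls) {
  cohort$truth$gene_class$gene[cohort$truth$gene_class$class == cls]
}

# Per-gene tumor-content covariate aligned to metadata sample order.
gene_covariate <- function(cohort, g) {
  md <- cohort$metadata
  te <- cohort$truth$tissue_expression
  te <- te[te$gene == g, ]
  tc <- compute_tumor_content(
    dplyr::inner_join(te, md[, c("sample_id", "group", "tumor_fraction")],
                      by = "sample_id")
  )
  x <- stats::setNames(rep(0, nrow(md)), md$sample_id)
  x[tc$sample_id] <- tc$covariate
  x[md$sample_id]
}
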