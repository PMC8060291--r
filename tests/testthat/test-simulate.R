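test_that("dark and dcb genes are silent in every non-cancer sample", {
  co <- tiny_cohort(seed = 3)
  m <- tbl_to_matrix(co$counts)
  nc <- co$metadata$sample_id[co$metadata$group == "noncancer"]
  for (cls in c("dark", "dcb")) {
    silent <- m[genes_of_class(co, cls), nc, drop = FALSE]
    expect_true(all(silent == 0), label = paste(cls, "genes zero in non-cancer"))
  }
  # outlier genes carry exactly one non-zero entry, in a cancer sample
  for (g in genes_of_class(co, "outlier_fp")) {
    nz <- which(m[g, ] > 0)
    expect_length(nz, 1)
    expect_true(names(nz) %in% co$metadata$sample_id[co$metadata$group == "cancer"])
  }
})

test_that("a fixed seed fixes every output bit", {
  cfg <- cohort_config(n_noncancer = 8, n_cancer = 6, n_background_genes = 30,
                       seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- cohort_config(n_noncancer = 8, n_cancer = 6, n_background_genes = 30,
                        seed = 43)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("background counts follow the NB(m, alpha) mean/variance law", {
  # degenerate intervals pin the parameters: m = 10 counts, alpha = 0.3
  cfg <- cohort_config(
    n_noncancer = 1000, n_cancer = 1000, n_background_genes = 1,
    n_dark_genes = 0, n_dcb_genes = 0, n_bimodal_fp_genes = 0,
    n_outlier_fp_genes = 0, depth_mean = 1e6, depth_cv = 0,
    background_log_mean_range = c(1, 1), dispersion_range = c(0.3, 0.3),
    seed = 7
  )
  y <- as.numeric(tbl_to_matrix(simulate_cohort(cfg)$counts))
  m <- 10
  v <- m + 0.3 * m^2 # 40
  expect_equal(mean(y), m, tolerance = 4 * sqrt(v / length(y)) / m)
  # variance of the sample variance for NB; generous Monte-Carlo band
  expect_gt(var(y), v * 0.85)
  expect_lt(var(y), v * 1.15)
})

test_that("dcb-gene counts scale with tumor fraction x tissue expression x depth", {
  cfg <- cohort_config(
    n_noncancer = 10, n_cancer = 600, n_background_genes = 10,
    n_dark_genes = 0, n_dcb_genes = 2, n_bimodal_fp_genes = 0,
    n_outlier_fp_genes = 0, depth_mean = 1e6, depth_cv = 0,
    tumor_fraction_range = c(0.1, 0.1), dcb_tissue_expr_range = c(200, 200),
    dispersion_range = c(0.3, 0.3), seed = 5
  )
  co <- simulate_cohort(cfg)
  m <- tbl_to_matrix(co$counts)
  ca <- co$metadata$sample_id[co$metadata$group == "cancer"]
  mu <- 0.1 * 200 * 1e6 / 1e6 # 20 counts per cancer sample
  v <- mu + 0.3 * mu^2
  for (g in genes_of_class(co, "dcb")) {
    expect_equal(mean(m[g, ca]), mu, tolerance = 3 * sqrt(v / length(ca)) / mu)
  }
})

test_that("tissue mixtures reproduce X beta exactly without noise", {
  ref <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        t1 = c(3, 2, 1), t2 = c(1, 5, 6))
  sig <- suppressWarnings(select_signature_genes(ref, k = 2))
  # unit vector returns the corresponding signature column
  y1 <- simulate_tissue_mixture(sig, c(1, 0), noise_sd = 0)
  expect_equal(y1$rpm, unname(sig$X[, "t1"]))
  # all-zero fractions return the zero vector
  expect_equal(simulate_tissue_mixture(sig, c(0, 0), noise_sd = 0)$rpm,
               rep(0, 3))
  # hand-computed 2-tissue, 3-gene combination
  y2 <- simulate_tissue_mixture(sig, c(0.3, 0.7), noise_sd = 0)
  expect_equal(y2$rpm, c(0.3 * 3 + 0.7 * 1, 0.3 * 2 + 0.7 * 5, 0.3 * 1 + 0.7 * 6))
  expect_error(simulate_tissue_mixture(sig, c(0.5, 0.3, 0.2)), "tissues")
  expect_error(simulate_tissue_mixture(sig, c(0.8, 0.5)), "sum")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_noncancer = 0), "at least one sample")
  expect_error(cohort_config(tumor_fraction_range = c(0, 0.5)), "strictly inside")
  expect_error(cohort_config(dispersion_range = c(0.5, 0.1)), "lower <= upper")
  # degenerate (zero-width) intervals are allowed
  expect_s3_class(cohort_config(dispersion_range = c(0.3, 0.3)), "cohort_config")
})

test_that("truth object covers every gene exactly once and fractions are valid", {
  co <- tiny_cohort(seed = 9)
  expect_setequal(co$truth$gene_class$gene, co$counts$gene)
  expect_false(anyDuplicated(co$truth$gene_class$gene) > 0)
  fr <- co$truth$mixture_fractions
  sums <- tapply(fr$fraction, fr$sample_id, sum)
  expect_true(all(fr$fraction >= 0))
  expect_true(all(sums <= 1 + 1e-9))
  tf <- co$truth$tumor_fraction$tumor_fraction
  expect_true(all(tf > 0 & tf < 1))
})
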