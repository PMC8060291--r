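heterode_inputs <- function(co) {
  md <- co$metadata
  tc <- compute_tumor_content(
    dplyr::inner_join(co$truth$tissue_expression,
                      md[, c("sample_id", "group", "tumor_fraction")],
                      by = "sample_id")
  )
  list(md = md, tc = tc)
}

test_that("heteroDE recovers planted dcb genes and excludes planted FPs", {
  co <- strong_cohort(6)
  inp <- heterode_inputs(co)
  expr <- compute_rpm(co$counts, inp$md)
  dark <- identify_dark_channels(expr, inp$md)
  res <- suppressWarnings(
    run_heterode(co$counts, inp$md, inp$tc, genes = dark$gene, seed = 6)
  )
  expect_setequal(res$gene[res$final_call], genes_of_class(co, "dcb"))
  # final_call implies significant
  expect_true(all(res$significant[res$final_call]))
  # pure dark genes are all-zero: non-converged fits carry no p-value
  darkonly <- res[res$gene %in% genes_of_class(co, "dark") & !res$prefiltered, ]
  if (nrow(darkonly)) expect_true(all(is.na(darkonly$p_value)))
})

test_that("the run is invariant to gene and sample order", {
  co <- simulate_cohort(strong_config(8, n_noncancer = 20, n_cancer = 20,
                                      n_background_genes = 60,
                                      n_dark_genes = 10))
  inp <- heterode_inputs(co)
  genes <- co$counts$gene[1:40]
  res <- suppressWarnings(
    run_heterode(co$counts, inp$md, inp$tc, genes = genes, seed = 8)
  )
  withr::local_seed(2)
  counts_p <- co$counts[sample(nrow(co$counts)),
                        c(1, 1 + sample(nrow(inp$md)))]
  md_p <- inp$md[sample(nrow(inp$md)), ]
  res_p <- suppressWarnings(
    run_heterode(counts_p, md_p, inp$tc, genes = genes, seed = 8)
  )
  expect_equal(as.data.frame(res_p), as.data.frame(res))
})

test_that("null genes rarely reach a final call and flags gate significance", {
  withr::local_seed(15)
  n <- 40
  md <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:(2 * n)),
    group = rep(c("noncancer", "cancer"), each = n),
    tumor_fraction = c(rep(NA, n), runif(n, 0.01, 0.1)),
    total_counts = rep(1e6, 2 * n)
  )
  genes <- sprintf("g%03d", 1:500)
  counts <- dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(matrix(rnbinom(500 * 2 * n, size = 1 / 0.3, mu = 20),
                             nrow = 500, dimnames = list(NULL, md$sample_id)))
  )
  tc <- compute_tumor_content(tidyr::crossing(
    gene = genes,
    md[md$group == "cancer", c("sample_id", "group", "tumor_fraction")]
  ) |> dplyr::mutate(tissue_expression_rpm = runif(dplyr::n(), 1, 100)))
  res <- suppressWarnings(run_heterode(counts, md, tc, seed = 15))
  expect_lte(sum(res$final_call), 40) # ~ 0.05 x 500 with headroom
  # flag gating: a significant gene flagged bimodal must not be called
  if (any(res$significant & !is.na(res$bimodal_flag) & res$bimodal_flag)) {
    expect_false(any(res$final_call[res$bimodal_flag & res$significant]))
  }
  expect_error(run_heterode(counts, md[0, ], tc), "sample")
})
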