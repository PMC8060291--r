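make_called_cohort <- function(seed = 2) {
  co <- strong_cohort(seed)
  md <- co$metadata
  expr <- compute_rpm(co$counts, md)
  dark <- identify_dark_channels(expr, md)
  list(co = co, md = md, expr = expr, dark = dark)
}

test_that("DCB criteria are enforced gene-wise within the dark set", {
  env <- make_called_cohort()
  calls <- call_dcbs(env$co$counts, env$expr, env$md, env$dark, "breast")
  # planted dcb genes pass; every passing gene satisfies all three criteria
  planted <- genes_of_class(env$co, "dcb")
  expect_true(all(planted %in% calls$gene[calls$passed]))
  passed <- calls[calls$passed, ]
  expect_true(all(passed$n_detected_in_cancer >= 2))
  expect_true(all(passed$second_highest_rpm > 0.1))
  expect_true(all(passed$de_pvalue < attr(calls, "de_alpha")))
  expect_equal(attr(calls, "de_alpha"), 0.2) # breast default
  calls_lung <- call_dcbs(env$co$counts, env$expr, env$md, env$dark, "lung")
  expect_equal(attr(calls_lung, "de_alpha"), 0.02)
  expect_error(
    call_dcbs(env$co$counts, env$expr, env$md, env$dark, "melanoma"),
    "not present"
  )
})

test_that("single-outlier and low-abundance genes fail the criteria", {
  env <- make_called_cohort()
  calls <- call_dcbs(env$co$counts, env$expr, env$md, env$dark, "breast")
  # planted outlier genes are dark but detected in at most 1 cancer sample
  ofp <- intersect(genes_of_class(env$co, "outlier_fp"), calls$gene)
  expect_true(length(ofp) > 0)
  expect_false(any(calls$passed[calls$gene %in% ofp]))
  # synthetic check of the second-highest-RPM rule: force a two-sample gene
  # whose second detection sits below the threshold
  md <- env$md
  counts <- env$co$counts
  ca <- md$sample_id[md$group == "cancer" & md$cancer_type == "breast"][1:2]
  g_idx <- which(counts$gene == genes_of_class(env$co, "dark")[1])
  counts[g_idx, ca[1]] <- 5000L
  counts[g_idx, ca[2]] <- 1L # far below 0.1 RPM at these depths
  expr <- compute_rpm(counts, md)
  dark <- identify_dark_channels(expr, md)
  calls2 <- call_dcbs(counts, expr, md, dark, "breast")
  row <- calls2[calls2$gene == counts$gene[g_idx], ]
  expect_identical(row$n_detected_in_cancer, 2L)
  expect_lt(row$second_highest_rpm, 0.1)
  expect_false(row$passed)
})

test_that("calls are invariant to gene and sample order", {
  env <- make_called_cohort(seed = 4)
  calls <- call_dcbs(env$co$counts, env$expr, env$md, env$dark, "lung")
  withr::local_seed(1)
  gperm <- sample(nrow(env$co$counts))
  sperm <- c(1, 1 + sample(ncol(env$co$counts) - 1)) # keep gene column first
  counts_p <- env$co$counts[gperm, sperm]
  expr_p <- env$expr[gperm, sperm]
  md_p <- env$md[sample(nrow(env$md)), ]
  dark_p <- identify_dark_channels(expr_p, md_p)
  calls_p <- call_dcbs(counts_p, expr_p, md_p, dark_p, "lung")
  expect_equal(as.data.frame(calls_p), as.data.frame(calls))
})

test_that("tissue-specificity annotation categories are attached", {
  env <- make_called_cohort()
  planted <- genes_of_class(env$co, "dcb")
  ann <- tibble::tibble(
    gene = planted[1:3],
    tissue = c("lung", "breast", "lung"),
    category = c("Tissue Enriched", "Group Enriched", "Tissue Enhanced")
  )
  calls <- call_dcbs(env$co$counts, env$expr, env$md, env$dark, "breast",
                     annotation = ann)
  got <- calls[match(planted[1:3], calls$gene), ]
  expect_identical(got$tissue_specificity,
                   c("tissue_enriched", "group_enriched", "tissue_enhanced"))
  expect_identical(got$specific_tissue, c("lung", "breast", "lung"))
  expect_true(all(calls$tissue_specificity[!calls$gene %in% ann$gene] == "none"))
})
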