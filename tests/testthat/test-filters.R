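test_that("planted bimodal genes are flagged; unimodal and cancer-only are not", {
  flagged_planted <- flagged_unimodal <- logical(5)
  for (s in 1:5) {
    co <- strong_cohort(s)
    md <- co$metadata
    rpm <- tbl_to_matrix(compute_rpm(co$counts, md))
    g <- genes_of_class(co, "bimodal_fp")[1]
    flagged_planted[s] <- suppressWarnings(
      bimodal_fp_filter(rpm[g, md$sample_id], md$group, seed = s)$bimodal_flag
    )
    withr::with_seed(1000 + s, {
      vals <- rnbinom(nrow(md), size = 1 / 0.2, mu = 20)
    })
    flagged_unimodal[s] <- suppressWarnings(
      bimodal_fp_filter(vals, md$group, seed = s)$bimodal_flag
    )
  }
  expect_gte(sum(flagged_planted), 4)
  expect_lte(sum(flagged_unimodal), 1)

  # bimodal in the cancer group only (subtype-specific pattern): not flagged
  withr::local_seed(9)
  grp <- rep(c("noncancer", "cancer"), each = 30)
  vals <- c(rnorm(30, 40, 4), # unimodal non-cancer
            pmax(c(rpois(15, 0.1), rnorm(15, 40, 4)), 0)) # bimodal cancer
  res <- bimodal_fp_filter(vals, grp)
  expect_false(res$bimodal_flag)
  expect_lt(res$pi1_noncancer, 0.1)
  expect_error(bimodal_fp_filter(vals[1:10], grp[1:10]), "at least 6")
})

test_that("the Cook's refit flags single-outlier genes but not spread signal", {
  n_sig <- 0L
  n_flagged <- 0L
  for (s in 1:5) {
    co <- strong_cohort(s)
    md <- co$metadata
    cm <- tbl_to_matrix(co$counts)
    off <- log(md$total_counts)
    for (g in genes_of_class(co, "outlier_fp")) {
      fit <- suppressWarnings(
        fit_nbglm(cm[g, md$sample_id], gene_covariate(co, g), offset = off)
      )
      if (isTRUE(fit$converged) && !is.na(fit$p_value) && fit$p_value < 0.05) {
        n_sig <- n_sig + 1L
        n_flagged <- n_flagged +
          suppressWarnings(cooks_outlier_filter(fit)$outlier_flag)
      }
    }
    # a dcb gene carries signal across many cancer samples: refit stays
    # significant, so it is not flagged
    g_dcb <- genes_of_class(co, "dcb")[1]
    fit_dcb <- fit_nbglm(cm[g_dcb, md$sample_id], gene_covariate(co, g_dcb),
                         offset = off)
    expect_lt(fit_dcb$p_value, 0.05)
    expect_false(cooks_outlier_filter(fit_dcb)$outlier_flag)
  }
  expect_gte(n_sig, 5L) # the failure mode arises routinely
  expect_identical(n_flagged, n_sig) # and is always caught
})

test_that("losing the informative sample at n = 5 flags the gene", {
  # a single dominant count drives significance; without it the tiny refit
  # has nothing left, so the gene is flagged
  y <- c(1L, 0L, 2L, 1L, 80L)
  x <- c(-0.5, -0.2, 0.1, 0.2, 0.6)
  fit <- fit_nbglm(y, x)
  expect_lt(fit$p_value, 0.05)
  res <- suppressWarnings(cooks_outlier_filter(fit, alpha_cut = 0.05))
  expect_true(res$outlier_flag)
  expect_identical(res$dropped_index, 5L)
  expect_error(cooks_outlier_filter(fit_nbglm(rep(0L, 6), rnorm(6))),
               "converged")
})
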