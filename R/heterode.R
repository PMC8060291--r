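#' Run heteroDE: heterogeneous differential expression on tumor content
#'
#' Fits, for each candidate gene, the NB GLM
#' `K_ij ~ NB(mu_ij, alpha_i)`, `log(mu_ij) = gamma_i + x_ij beta_i`
#' ([fit_nbglm()]) where `x_ij` is the per-gene, per-sample tumor-content
#' covariate (log10 product for cancer samples, exactly 0 for non-cancer;
#' see [compute_tumor_content()]). Genes significant at `alpha_cut` are then
#' passed through the two false-positive filters: bimodality in both groups
#' ([bimodal_fp_filter()], on RPM) and the Cook's-distance single-outlier
#' refit ([cooks_outlier_filter()]). The final biomarker call requires
#' significance and both filters clean.
#'
#' An offset of `log(total_counts)` is included by default so counts are
#' compared on a common depth scale; `use_offset = FALSE` drops it and
#' models raw counts.
#'
#' @param counts Strict-count tibble (`gene` + sample columns).
#' @param metadata Sample metadata (`sample_id`, `group`, `total_counts`).
#' @param tumor_content Tibble from [compute_tumor_content()] with at least
#'   `gene`, `sample_id`, `covariate`, covering every cancer sample for
#'   every candidate gene.
#' @param genes Candidate genes to fit; default all genes passing the
#'   prefilter.
#' @param alpha_cut Significance cut-off for candidate biomarkers
#'   (default 0.05, unadjusted, as the primary discovery criterion).
#' @param adjust `"none"` (default) or `"BH"`; with `"BH"`, significance is
#'   `p_adjusted <= bh_q` instead of `p < alpha_cut`.
#' @param bh_q FDR level used when `adjust = "BH"` (default 0.01).
#' @param use_offset Include the `log(total_counts)` offset (default TRUE).
#' @param min_detected Prefilter: a gene must be detected (count > 0) in at
#'   least this many samples to be fitted (default 2).
#' @param seed Seed for the mixture-filter random starts.
#'
#' @return Tibble of class `heterode_result`: one row per candidate gene
#'   with `gamma`, `beta`, `alpha`, `p_value`, `p_adjusted`, `converged`,
#'   `prefiltered`, `significant`, `bimodal_flag`, `outlier_flag`,
#'   `final_call`. Filter flags are `NA` for genes the filters were not
#'   applied to (non-significant or non-converged).
#' @export
run_heterode <- function(counts, metadata, tumor_content, genes = NULL,
                         alpha_cut = 0.05, adjust = c("none", "BH"),
                         bh_q = 0.01, use_offset = TRUE, min_detected = 2L,
                         seed = 1L) {
  adjust <- match.arg(adjust)
  cm <- as_gene_matrix(counts, "counts")
  check_metadata(metadata, colnames(cm))
  if (!any(metadata$group == "cancer")) abort("no cancer samples in `metadata`.")
  if (!all(c("gene", "sample_id", "covariate") %in% names(tumor_content))) {
    abort("`tumor_content` needs columns gene, sample_id, covariate (see compute_tumor_content()).")
  }
  samples <- metadata$sample_id
  cm <- cm[, samples, drop = FALSE]
  is_cancer <- metadata$group == "cancer"
  totals <- resolve_totals(metadata, samples)
  off <- if (use_offset) log(totals) else NULL
  rpm <- sweep(cm, 2, totals, "/") * 1e6

  genes <- genes %||% rownames(cm)
  missing <- setdiff(genes, rownames(cm))
  if (length(missing)) {
    abort(paste0("candidate gene(s) absent from `counts`: ",
                 paste(head(missing, 5), collapse = ", ")))
  }

  cov_tbl <- tumor_content[tumor_content$gene %in% genes, c("gene", "sample_id", "covariate")]

  fit_one <- function(g) {
    y <- cm[g, ]
    if (sum(y > 0) < min_detected) {
      return(tibble::tibble(
        gene = g, gamma = NA_real_, beta = NA_real_, alpha = NA_real_,
        p_value = NA_real_, converged = NA, prefiltered = TRUE
      ))
    }
    cv <- cov_tbl[cov_tbl$gene == g, ]
    x <- setNames(rep(0, length(samples)), samples)
    x[cv$sample_id[cv$sample_id %in% samples]] <-
      cv$covariate[cv$sample_id %in% samples]
    miss_ca <- samples[is_cancer & !samples %in% cv$sample_id]
    if (length(miss_ca)) {
      abort(paste0("tumor content missing for cancer sample(s) ",
                   paste(head(miss_ca, 5), collapse = ", "),
                   " at gene ", g, "."))
    }
    fit <- fit_nbglm(y, x, offset = off)
    tibble::tibble(
      gene = g, gamma = fit$gamma, beta = fit$beta, alpha = fit$alpha,
      p_value = fit$p_value, converged = fit$converged, prefiltered = FALSE
    )
  }

  res <- purrr::map(genes, fit_one) |> purrr::list_rbind()
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res$significant <- if (adjust == "BH") {
    !is.na(res$p_adjusted) & res$p_adjusted <= bh_q
  } else {
    !is.na(res$p_value) & res$p_value < alpha_cut
  }

  grp <- metadata$group
  flags <- purrr::map(seq_len(nrow(res)), function(i) {
    if (!isTRUE(res$significant[i])) {
      return(tibble::tibble(bimodal_flag = NA, outlier_flag = NA))
    }
    g <- res$gene[i]
    y <- cm[g, ]
    bf <- if (sum(grp == "noncancer") >= 6L && sum(grp == "cancer") >= 6L) {
      bimodal_fp_filter(rpm[g, ], grp, seed = seed)$bimodal_flag
    } else {
      NA
    }
    cv <- cov_tbl[cov_tbl$gene == g, ]
    x <- setNames(rep(0, length(samples)), samples)
    x[cv$sample_id[cv$sample_id %in% samples]] <-
      cv$covariate[cv$sample_id %in% samples]
    fit <- fit_nbglm(y, x, offset = off)
    of <- suppressWarnings(cooks_outlier_filter(fit, alpha_cut = alpha_cut)$outlier_flag)
    tibble::tibble(bimodal_flag = bf, outlier_flag = of)
  }) |> purrr::list_rbind()
  res <- dplyr::bind_cols(res, flags)
  res$final_call <- isTRUE_vec(res$significant) &
    !isTRUE_vec(res$bimodal_flag) & !isTRUE_vec(res$outlier_flag)

  class(res) <- c("heterode_result", class(res))
  attr(res, "alpha_cut") <- alpha_cut
  attr(res, "adjust") <- adjust
  attr(res, "bh_q") <- bh_q
  attr(res, "use_offset") <- use_offset
  res
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.heterode_result <- function(x, ...) {
  need <- c("prefiltered", "significant", "final_call")
  if (all(need %in% names(x))) {
    cat(sprintf("<heterode_result> %d genes fitted, %d significant, %d final calls\n",
                sum(!x$prefiltered, na.rm = TRUE), sum(x$significant, na.rm = TRUE),
                sum(x$final_call, na.rm = TRUE)))
  }
  NextMethod()
}

#' Volcano-style plot of heteroDE results
#'
#' @param object A `heterode_result` from [run_heterode()].
#' @param ... Unused.
#' @return A ggplot object of tumor-content coefficient versus -log10 p,
#'   colored by final call, with filtered-out significant genes marked.
#' @export
autoplot.heterode_result <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$final_call ~ "biomarker",
        .data$significant ~ "filtered false positive",
        TRUE ~ "not significant"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "tumor-content coefficient (beta)",
                  y = expression(-log[10](p)), colour = NULL) +
    ggplot2::theme_minimal()
}
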