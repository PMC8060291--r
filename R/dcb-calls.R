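#' Call dark-channel biomarkers for one cancer type
#'
#' Evaluates every dark-channel gene against the three DCB criteria for the
#' given cancer type:
#' \enumerate{
#'   \item detected (strict count > 0) in at least 2 samples of the cancer
#'     group;
#'   \item RPM in the second-highest cancer sample greater than
#'     `rpm_threshold` (default 0.1);
#'   \item differentially expressed versus the non-cancer group
#'     ([nb_two_group_test()]) at the cancer-type-specific level `de_alpha`
#'     (defaults: 0.02 for lung, 0.2 for breast, 0.05 otherwise).
#' }
#' Samples of other cancer types are excluded from the comparison. Every
#' evaluated gene is returned with its criterion values and pass flag, so
#' near-misses are inspectable.
#'
#' @param counts Strict-count tibble (`gene` + sample columns).
#' @param expr Matching RPM tibble from [compute_rpm()].
#' @param metadata Sample metadata (`sample_id`, `group`, `cancer_type`,
#'   `total_counts`).
#' @param dark Dark-channel table from [identify_dark_channels()].
#' @param cancer_type Cancer type to call biomarkers for (must appear in
#'   `metadata$cancer_type`).
#' @param de_alpha Differential-expression significance level; `NULL` picks
#'   the cancer-type default.
#' @param rpm_threshold Second-highest-sample RPM threshold (default 0.1).
#' @param annotation Optional tissue-specificity annotation tibble with
#'   columns `gene`, `tissue`, `category` (categories "Tissue Enriched",
#'   "Group Enriched", "Tissue Enhanced"; all three count as
#'   tissue-specific).
#'
#' @return Tibble of class `dcb_calls`: one row per dark gene with
#'   `n_detected_in_cancer`, `second_highest_rpm`, `de_pvalue`,
#'   `log_fold_change`, `passed`, `tissue_specificity`, `specific_tissue`.
#' @export
call_dcbs <- function(counts, expr, metadata, dark, cancer_type,
                      de_alpha = NULL, rpm_threshold = 0.1, annotation = NULL) {
  cm <- as_gene_matrix(counts, "counts")
  em <- as_gene_matrix(expr, "expr")
  check_metadata(metadata, colnames(cm))
  if (!identical(dim(cm), dim(em)) || !identical(rownames(cm), rownames(em))) {
    abort("`counts` and `expr` must share genes and samples.")
  }
  types <- unique(metadata$cancer_type[metadata$group == "cancer"])
  if (!cancer_type %in% types) {
    abort(sprintf("cancer type '%s' not present in metadata (found: %s).",
                  cancer_type, paste(types, collapse = ", ")))
  }
  de_alpha <- de_alpha %||% default_de_alpha(cancer_type)

  dark_genes <- intersect(dark$gene, rownames(cm))
  ca_samples <- metadata$sample_id[metadata$group == "cancer" &
                                     !is.na(metadata$cancer_type) &
                                     metadata$cancer_type == cancer_type]
  nc_samples <- metadata$sample_id[metadata$group == "noncancer"]
  if (length(ca_samples) < 2L) {
    abort(sprintf("fewer than 2 samples of cancer type '%s'.", cancer_type))
  }
  test_samples <- c(nc_samples, ca_samples)
  grp <- factor(rep(c("noncancer", "cancer"), c(length(nc_samples), length(ca_samples))),
                levels = c("noncancer", "cancer"))
  totals <- resolve_totals(metadata, test_samples)

  res <- purrr::map(dark_genes, function(g) {
    ca_counts <- cm[g, ca_samples]
    ca_rpm <- em[g, ca_samples]
    n_det <- sum(ca_counts > 0)
    second <- unname(sort(ca_rpm, decreasing = TRUE)[2])
    de <- nb_two_group_test(cm[g, test_samples], totals, grp)
    tibble::tibble(
      gene = g,
      n_detected_in_cancer = n_det,
      second_highest_rpm = second,
      de_pvalue = de$p_value,
      log_fold_change = de$estimate,
      passed = n_det >= 2L && second > rpm_threshold && de$p_value < de_alpha
    )
  }) |> purrr::list_rbind()

  res <- annotate_tissue_specificity(res, annotation)
  res <- dplyr::arrange(res, .data$gene)
  class(res) <- c("dcb_calls", class(res))
  attr(res, "cancer_type") <- cancer_type
  attr(res, "de_alpha") <- de_alpha
  attr(res, "rpm_threshold") <- rpm_threshold
  res
}

default_de_alpha <- function(cancer_type) {
  switch(tolower(cancer_type), lung = 0.02, breast = 0.2, 0.05)
}

annotate_tissue_specificity <- function(res, annotation) {
  if (is.null(annotation) || !nrow(res)) {
    res$tissue_specificity <- "none"
    res$specific_tissue <- NA_character_
    return(res)
  }
  if (!all(c("gene", "tissue", "category") %in% names(annotation))) {
    abort("`annotation` needs columns gene, tissue, category.")
  }
  canonical <- c(
    "tissue enriched" = "tissue_enriched",
    "group enriched" = "group_enriched",
    "tissue enhanced" = "tissue_enhanced"
  )
  ann <- annotation |>
    dplyr::mutate(category = unname(canonical[tolower(.data$category)])) |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  res |>
    dplyr::left_join(ann, by = "gene") |>
    dplyr::mutate(
      tissue_specificity = dplyr::coalesce(.data$category, "none"),
      specific_tissue = .data$tissue
    ) |>
    dplyr::select(-dplyr::any_of(c("category", "tissue")))
}

#' @export
print.dcb_calls <- function(x, ...) {
  cat(sprintf("<dcb_calls> cancer type '%s': %d dark genes evaluated, %d passed (de_alpha = %g)\n",
              attr(x, "cancer_type"), nrow(x), sum(x$passed), attr(x, "de_alpha")))
  NextMethod()
}
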