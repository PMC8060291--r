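#' Run the full dark-channel biomarker discovery pipeline
#'
#' Orchestrates the stages on one cohort: RPM normalization
#' ([compute_rpm()]), dark-channel identification
#' ([identify_dark_channels()]), per-cancer-type DCB calling
#' ([call_dcbs()]), heteroDE on the candidate genes ([run_heterode()], run
#' only when tumor fractions and matched-tumor expression are available),
#' and the union biomarker report ([merge_biomarker_sets()]). The run is
#' fully deterministic given the inputs and `seed`.
#'
#' @param counts Strict-count tibble (`gene` + sample columns).
#' @param metadata Sample metadata (`sample_id`, `group`, `cancer_type`,
#'   `total_counts`, optionally `tumor_fraction`).
#' @param tissue_expression Optional matched-tumor expression tibble with
#'   columns `gene`, `sample_id`, `tissue_expression_rpm`; required for the
#'   heteroDE stage.
#' @param annotation Optional tissue-specificity annotation (see
#'   [call_dcbs()]).
#' @param cancer_types Cancer types to call DCBs for; default every type in
#'   `metadata`.
#' @param sd_threshold,rpm_threshold,de_alpha,alpha_cut,bh_q,tumor_content_floor,use_offset
#'   Stage parameters; `de_alpha` is a named vector per cancer type
#'   (defaults lung 0.02, breast 0.2, otherwise 0.05).
#' @param heterode_candidates `"dark"` (default) to evaluate heteroDE on the
#'   dark-channel genes, or `"all"` for every gene.
#' @param heterode_adjust `"none"` (default) or `"BH"` multiplicity handling
#'   for the heteroDE stage.
#' @param seed Seed for the (local) randomness of the mixture filter starts.
#'
#' @return A list of class `run_report`: `config` (echo of every threshold),
#'   `stage_counts`, `dark`, `dcb_calls` (named list per cancer type),
#'   `heterode` (or NULL with the skip reason in `warnings`), `biomarkers`
#'   (union table) and `warnings`.
#' @export
run_pipeline <- function(counts, metadata,
                         tissue_expression = NULL, annotation = NULL,
                         cancer_types = NULL,
                         sd_threshold = 0.1, rpm_threshold = 0.1,
                         de_alpha = NULL, alpha_cut = 0.05, bh_q = 0.01,
                         tumor_content_floor = 1e-6, use_offset = TRUE,
                         heterode_candidates = c("dark", "all"),
                         heterode_adjust = c("none", "BH"),
                         seed = 1L) {
  heterode_candidates <- match.arg(heterode_candidates)
  heterode_adjust <- match.arg(heterode_adjust)
  cm <- as_gene_matrix(counts, "counts")
  check_metadata(metadata, colnames(cm))
  warnings <- character()

  config <- list(
    sd_threshold = sd_threshold, rpm_threshold = rpm_threshold,
    de_alpha = de_alpha, alpha_cut = alpha_cut, bh_q = bh_q,
    tumor_content_floor = tumor_content_floor, use_offset = use_offset,
    heterode_candidates = heterode_candidates,
    heterode_adjust = heterode_adjust, seed = seed
  )

  expr <- compute_rpm(counts, metadata)
  dark <- identify_dark_channels(expr, metadata, sd_threshold = sd_threshold)

  cancer_types <- cancer_types %||%
    unique(stats::na.omit(metadata$cancer_type[metadata$group == "cancer"]))
  dcb_calls <- list()
  for (ct in cancer_types) {
    alpha_ct <- if (!is.null(de_alpha) && ct %in% names(de_alpha)) {
      unname(de_alpha[[ct]])
    } else {
      NULL
    }
    dcb_calls[[ct]] <- call_dcbs(counts, expr, metadata, dark, ct,
                                 de_alpha = alpha_ct,
                                 rpm_threshold = rpm_threshold,
                                 annotation = annotation)
  }
  dcb_genes <- purrr::map(dcb_calls, ~ .x$gene[.x$passed])

  heterode <- NULL
  have_tf <- "tumor_fraction" %in% names(metadata) &&
    !anyNA(metadata$tumor_fraction[metadata$group == "cancer"])
  if (!have_tf) {
    warnings <- c(warnings, "heteroDE skipped: tumor_fraction missing for cancer samples.")
  } else if (is.null(tissue_expression)) {
    warnings <- c(warnings, "heteroDE skipped: matched-tumor tissue_expression not supplied.")
  } else {
    candidates <- if (heterode_candidates == "dark") dark$gene else rownames(cm)
    tc_input <- tissue_expression |>
      dplyr::filter(.data$gene %in% candidates) |>
      dplyr::inner_join(
        metadata |> dplyr::select("sample_id", "group", "tumor_fraction"),
        by = "sample_id"
      )
    tumor_content <- compute_tumor_content(tc_input, floor = tumor_content_floor)
    heterode <- run_heterode(counts, metadata, tumor_content,
                             genes = candidates, alpha_cut = alpha_cut,
                             adjust = heterode_adjust, bh_q = bh_q,
                             use_offset = use_offset, seed = seed)
  }
  heterode_genes <- if (is.null(heterode)) character() else heterode$gene[heterode$final_call]

  biomarkers <- merge_biomarker_sets(dcb_genes, heterode_genes)

  stage_counts <- tibble::tibble(
    stage = c("genes", "samples", "dark_channels",
              paste0("dcb_", names(dcb_calls)), "heterode_final", "biomarkers"),
    n = unname(c(nrow(cm), ncol(cm), nrow(dark),
                 vapply(dcb_calls, function(x) sum(x$passed), integer(1)),
                 length(heterode_genes), nrow(biomarkers)))
  )

  structure(
    list(config = config, stage_counts = stage_counts, dark = dark,
         dcb_calls = dcb_calls, heterode = heterode,
         biomarkers = biomarkers, warnings = warnings),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$stage_counts, n = Inf)
  if (length(x$warnings)) cat("warnings:\n", paste0("  - ", x$warnings, "\n"), sep = "")
  invisible(x)
}

#' Merge DCB and heteroDE biomarker sets
#'
#' Deduplicated union of the per-cancer-type DCB gene lists and the heteroDE
#' gene list, with provenance: which method(s) and cancer type(s) selected
#' each gene.
#'
#' @param dcb_genes Named list of character vectors (one per cancer type),
#'   or a single character vector.
#' @param heterode_genes Character vector of heteroDE final calls.
#'
#' @return Tibble with columns `gene`, `methods` (e.g. "dcb",
#'   "dcb+heterode"), `cancer_types` (comma-separated, for the DCB side).
#' @export
#' @examples
#' merge_biomarker_sets(list(lung = c("A", "B"), breast = c("B", "C")), c("C", "D"))
merge_biomarker_sets <- function(dcb_genes, heterode_genes = character()) {
  if (is.character(dcb_genes)) dcb_genes <- list(all = dcb_genes)
  dcb_tbl <- purrr::imap(dcb_genes, ~ tibble::tibble(gene = .x, cancer_type = .y)) |>
    purrr::list_rbind()
  if (!nrow(dcb_tbl)) dcb_tbl <- tibble::tibble(gene = character(), cancer_type = character())
  dcb_sum <- dcb_tbl |>
    dplyr::distinct() |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(cancer_types = paste(sort(unique(.data$cancer_type)), collapse = ","),
                     .groups = "drop")
  genes <- sort(unique(c(dcb_sum$gene, heterode_genes)))
  tibble::tibble(gene = genes) |>
    dplyr::left_join(dcb_sum, by = "gene") |>
    dplyr::mutate(
      in_dcb = .data$gene %in% dcb_sum$gene,
      in_heterode = .data$gene %in% heterode_genes,
      methods = dplyr::case_when(
        .data$in_dcb & .data$in_heterode ~ "dcb+heterode",
        .data$in_dcb ~ "dcb",
        TRUE ~ "heterode"
      )
    ) |>
    dplyr::select("gene", "methods", "cancer_types")
}
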