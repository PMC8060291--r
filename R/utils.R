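# Internal helpers shared across modules.

# A counts/expression table is a tibble whose first column ("gene") holds gene
# IDs and whose remaining columns are samples. These helpers convert between
# that user-facing shape and the numeric matrix used internally.
as_gene_matrix <- function(tbl, what = "counts") {
  if (!is.data.frame(tbl) || ncol(tbl) < 2L) {
    abort(sprintf("`%s` must be a data frame with a gene column plus >= 1 sample column.", what))
  }
  gene_col <- names(tbl)[1L]
  genes <- as.character(tbl[[gene_col]])
  if (anyDuplicated(genes)) {
    abort(sprintf("`%s` contains duplicated gene IDs.", what))
  }
  m <- as.matrix(tbl[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("sample columns of `%s` must be numeric.", what))
  rownames(m) <- genes
  m
}

gene_matrix_to_tibble <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(gene = rownames(m)),
    tibble::as_tibble(m)
  )
}

# Resolve per-sample totals from a named vector or a metadata-like data frame
# with sample_id + total_counts columns, aligned to `samples`.
resolve_totals <- function(totals, samples) {
  if (is.data.frame(totals)) {
    if (!all(c("sample_id", "total_counts") %in% names(totals))) {
      abort("metadata-style `totals` needs `sample_id` and `total_counts` columns.")
    }
    tot <- setNames(totals$total_counts, totals$sample_id)
  } else if (is.numeric(totals) && !is.null(names(totals))) {
    tot <- totals
  } else {
    abort("`totals` must be a named numeric vector or a data frame with sample_id/total_counts.")
  }
  missing <- setdiff(samples, names(tot))
  if (length(missing)) {
    abort(paste0("no total counts for sample(s): ", paste(missing, collapse = ", ")))
  }
  tot[samples]
}

check_metadata <- function(metadata, samples = NULL) {
  req <- c("sample_id", "group")
  if (!is.data.frame(metadata) || !all(req %in% names(metadata))) {
    abort("`metadata` must be a data frame with at least `sample_id` and `group` columns.")
  }
  bad <- setdiff(unique(metadata$group), c("noncancer", "cancer"))
  if (length(bad)) {
    abort(paste0("`group` must be 'noncancer' or 'cancer'; found: ", paste(bad, collapse = ", ")))
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, metadata$sample_id)
    extra <- setdiff(metadata$sample_id, samples)
    if (length(miss) || length(extra)) {
      abort(paste0(
        "sample IDs in the matrix and metadata disagree.",
        if (length(miss)) paste0(" Missing from metadata: ", paste(head(miss, 5), collapse = ", "), ".") else "",
        if (length(extra)) paste0(" Absent from matrix: ", paste(head(extra, 5), collapse = ", "), ".") else ""
      ))
    }
  }
  invisible(metadata)
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}
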