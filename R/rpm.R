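#' Reads-per-million normalization of strict counts
#'
#' Converts collapsed strict-read counts to RPM:
#' `rpm(g, s) = counts(g, s) * 1e6 / totals(s)`. The denominator is the
#' library-wide total of collapsed strict mapped reads, supplied explicitly
#' (not recomputed from the matrix) because a filtered matrix may omit genes
#' that still contribute to the library total.
#'
#' @param counts Tibble with a `gene` column plus one non-negative integer
#'   column per sample.
#' @param totals Named numeric vector of per-sample totals, or a metadata
#'   data frame with `sample_id` and `total_counts` columns.
#'
#' @return Tibble of the same shape as `counts`, values in RPM.
#' @export
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10L, 0L), s2 = c(5L, 2L))
#' compute_rpm(counts, c(s1 = 1e6, s2 = 2e6))
compute_rpm <- function(counts, totals) {
  m <- as_gene_matrix(counts, "counts")
  if (!is_count_vector(as.numeric(m))) {
    abort("`counts` must contain non-negative integer values.")
  }
  tot <- resolve_totals(totals, colnames(m))
  zero <- names(tot)[tot <= 0]
  if (length(zero)) {
    abort(paste0("zero or negative library total for sample(s): ",
                 paste(zero, collapse = ", ")))
  }
  rpm <- sweep(m, 2, tot, "/") * 1e6
  gene_matrix_to_tibble(rpm)
}

#' Identify dark channels in non-cancer plasma
#'
#' A dark channel is a gene with no appreciable background expression in
#' non-cancer plasma: its median RPM across non-cancer samples is exactly 0
#' and its RPM standard deviation is below `sd_threshold`. The SD uses the
#' sample convention (n - 1 denominator); the convention is recorded on the
#' result so runs are reproducible either way.
#'
#' @param expr RPM tibble as returned by [compute_rpm()].
#' @param metadata Sample metadata with `sample_id` and `group`
#'   (`"noncancer"`/`"cancer"`) columns.
#' @param sd_threshold Maximum non-cancer RPM standard deviation (default 0.1).
#' @param all If `TRUE`, return every gene with a logical `dark` column;
#'   otherwise (default) only the dark channels.
#'
#' @return Tibble with columns `gene`, `median_rpm`, `sd_rpm` (and `dark` when
#'   `all = TRUE`), with attributes `sd_threshold` and `sd_convention`.
#' @export
identify_dark_channels <- function(expr, metadata, sd_threshold = 0.1, all = FALSE) {
  m <- as_gene_matrix(expr, "expr")
  check_metadata(metadata, colnames(m))
  nc <- metadata$sample_id[metadata$group == "noncancer"]
  if (!length(nc)) abort("no non-cancer samples in `metadata`.")
  if (length(nc) < 2L) abort("at least 2 non-cancer samples are required.")
  sub <- m[, nc, drop = FALSE]
  med <- unname(apply(sub, 1, median))
  sds <- unname(apply(sub, 1, sd))
  out <- tibble::tibble(
    gene = rownames(m),
    median_rpm = med,
    sd_rpm = sds,
    dark = med == 0 & sds < sd_threshold
  )
  if (!all) out <- dplyr::filter(out, .data$dark) |> dplyr::select(-"dark")
  attr(out, "sd_threshold") <- sd_threshold
  attr(out, "sd_convention") <- "sample (n-1)"
  attr(out, "n_noncancer") <- length(nc)
  out
}
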