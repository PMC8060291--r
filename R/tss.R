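#' Tissue specificity score
#'
#' For each gene j with median expression \eqn{x_{ij}} in tissue i, the tissue
#' specificity score is \eqn{TSS_j = \max_i (x_{ij} / \sum_i x_{ij})}, with the
#' arg-max tissue recorded alongside. A score of 1 means the gene is expressed
#' in a single tissue; 1/p means uniform expression over p tissues. Genes with
#' zero total expression get `NA` scores and are excluded from signature
#' selection.
#'
#' @param reference Tibble of median expression in RPM: a `gene` column plus
#'   one column per tissue (GTEx-style, genes in rows).
#'
#' @return Tibble with columns `gene`, `tss`, `tissue` (arg-max) and
#'   `expressed` (FALSE where the gene is silent in every tissue).
#' @export
#' @examples
#' ref <- tibble::tibble(gene = c("a", "b"), liver = c(6, 1), lung = c(3, 1),
#'                       breast = c(1, 1))
#' tissue_specificity_score(ref)
tissue_specificity_score <- function(reference) {
  m <- as_gene_matrix(reference, "reference")
  if (ncol(m) < 1L) abort("`reference` must contain at least one tissue column.")
  if (any(m < 0)) abort("`reference` must be non-negative.")
  tot <- unname(rowSums(m))
  share <- m / ifelse(tot > 0, tot, NA_real_)
  idx <- apply(m, 1, which.max)
  tibble::tibble(
    gene = rownames(m),
    tss = unname(ifelse(tot > 0, share[cbind(seq_len(nrow(m)), idx)], NA_real_)),
    tissue = unname(ifelse(tot > 0, colnames(m)[idx], NA_character_)),
    expressed = tot > 0
  )
}

#' Select tissue signature genes by specificity score
#'
#' For each tissue, picks the `k` genes with the highest tissue specificity
#' score whose arg-max tissue is that tissue. Ties at rank k are broken by
#' descending TSS then ascending gene ID, so the result is independent of
#' input row order. Tissues with fewer than `k` candidates contribute all of
#' them, with a warning.
#'
#' @param reference Tissue median-expression tibble (see
#'   [tissue_specificity_score()]).
#' @param k Signature genes per tissue (default 20).
#'
#' @return A `tissue_signature` object: list with `genes`, `tissues`, the
#'   genes-by-tissues median-expression matrix `X` (RPM), and the per-gene
#'   `tss` table.
#' @export
select_signature_genes <- function(reference, k = 20) {
  if (!is.data.frame(reference) || !nrow(reference)) {
    abort("`reference` must be a non-empty data frame.")
  }
  if (k < 1) abort("`k` must be >= 1.")
  tss <- tissue_specificity_score(reference)
  m <- as_gene_matrix(reference, "reference")
  picked <- tss |>
    dplyr::filter(.data$expressed) |>
    dplyr::arrange(.data$tissue, dplyr::desc(.data$tss), .data$gene) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
  short <- picked |>
    dplyr::count(.data$tissue) |>
    dplyr::filter(.data$n < k)
  if (nrow(short)) {
    warn(paste0("fewer than k = ", k, " candidate genes for tissue(s): ",
                paste(short$tissue, collapse = ", ")))
  }
  genes <- sort(picked$gene)
  X <- m[genes, , drop = FALSE]
  structure(
    list(genes = genes, tissues = colnames(m), X = X,
         tss = picked |> dplyr::arrange(.data$gene), k = k),
    class = "tissue_signature"
  )
}

#' @export
print.tissue_signature <- function(x, ...) {
  cat(sprintf("<tissue_signature> %d genes x %d tissues (k = %d per tissue)\n",
              length(x$genes), length(x$tissues), x$k))
  invisible(x)
}
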