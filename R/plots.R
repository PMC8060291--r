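#' Heatmap of dark-channel gene expression across samples
#'
#' Log-scaled RPM tile plot of selected genes (by default the dark channels
#' with the highest cancer-group signal), samples grouped by cancer status
#' -- the standard way to eyeball recurrent cancer-specific detection inside
#' otherwise dark regions.
#'
#' @param expr RPM tibble from [compute_rpm()].
#' @param metadata Sample metadata (`sample_id`, `group`).
#' @param genes Genes to show; default the 25 genes with the highest total
#'   cancer-group RPM among `dark$gene`.
#' @param dark Optional dark-channel table used for the default gene choice.
#' @return A ggplot object.
#' @export
plot_dark_channels <- function(expr, metadata, genes = NULL, dark = NULL) {
  m <- as_gene_matrix(expr, "expr")
  check_metadata(metadata, colnames(m))
  if (is.null(genes)) {
    pool <- if (!is.null(dark)) intersect(dark$gene, rownames(m)) else rownames(m)
    ca <- metadata$sample_id[metadata$group == "cancer"]
    score <- rowSums(m[pool, ca, drop = FALSE])
    genes <- pool[order(-score)][seq_len(min(25L, length(pool)))]
  }
  ord <- metadata |> dplyr::arrange(.data$group, .data$sample_id)
  long <- tibble::as_tibble(m[genes, , drop = FALSE], rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "rpm") |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = ord$sample_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene,
                                     fill = log10(.data$rpm + 0.01))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(log[10](RPM + 0.01))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
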