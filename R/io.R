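# Readers and writers for the plain-text interchange formats used around the
# pipeline: genes-x-samples count TSV (or MatrixMarket with sidecars),
# sample-metadata TSV, GTEx-style tissue median-expression TSV, HPA-style
# tissue-specificity TSV.

#' Read a genes-by-samples count matrix
#'
#' Accepts either a TSV whose first column holds gene IDs and whose header
#' holds sample IDs, or a MatrixMarket `.mtx` file with `<stem>.genes.txt`
#' and `<stem>.samples.txt` sidecar files (one ID per line).
#'
#' @param path Path to the `.tsv`/`.txt` or `.mtx` file.
#' @return Count tibble (`gene` + one integer column per sample).
#' @export
read_count_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    genes_f <- paste0(stem, ".genes.txt")
    samples_f <- paste0(stem, ".samples.txt")
    if (!file.exists(genes_f) || !file.exists(samples_f)) {
      abort("MatrixMarket input needs <stem>.genes.txt and <stem>.samples.txt sidecars.")
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_f)
    colnames(m) <- readLines(samples_f)
    storage.mode(m) <- "integer"
    return(gene_matrix_to_tibble(m))
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  names(tbl)[1] <- "gene"
  tbl |> dplyr::mutate(dplyr::across(-"gene", as.integer))
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `group`, and optionally `cancer_type`,
#' `subtype`, `tumor_fraction`, `total_counts`.
#'
#' @param path Path to the TSV.
#' @return Metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  check_metadata(md)
  md
}

#' Read a GTEx-style tissue median-expression reference
#'
#' TSV with genes in rows (first column gene IDs) and one column per tissue,
#' values in RPM.
#'
#' @param path Path to the TSV.
#' @return Reference tibble for [tissue_specificity_score()].
#' @export
read_tissue_reference <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  names(tbl)[1] <- "gene"
  tbl
}

#' Read an HPA-style tissue-specificity annotation
#'
#' TSV with columns `gene`, `tissue`, `category` ("Tissue Enriched",
#' "Group Enriched" or "Tissue Enhanced").
#'
#' @param path Path to the TSV.
#' @return Annotation tibble for [call_dcbs()].
#' @export
read_tissue_annotation <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `counts.tsv` (genes x samples), `metadata.tsv`, `truth.json` and
#' `tissue_reference.tsv` under `outdir`.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$counts, file.path(outdir, "counts.tsv"))
  readr::write_tsv(cohort$metadata, file.path(outdir, "metadata.tsv"))
  readr::write_tsv(cohort$tissue_reference, file.path(outdir, "tissue_reference.tsv"))
  jsonlite::write_json(cohort$truth, file.path(outdir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(outdir)
}
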