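#' Example biomarker gene sets from a breast/lung cfRNA discovery cohort
#'
#' Gene lists from a published whole-transcriptome cfRNA discovery analysis
#' of stage III breast and lung cancer plasma, bundled as a worked example
#' for [merge_biomarker_sets()] and [fisher_enrichment()]: 12 lung and 8
#' breast dark-channel biomarkers (one gene, WFDC2, shared between the two),
#' and 7 heteroDE biomarkers from the breast cohort (3 of which are also
#' DCBs). Alongside the lists, `annotation_counts` carries the cohort-level
#' counts needed for enrichment arithmetic: 57,820 annotated genes of which
#' 39,564 were never detected in non-cancer plasma; ~0.3% of the genome is
#' lung-specific and ~0.2% breast-specific; 6 of the 12 lung DCBs and 4 of
#' the 8 breast DCBs are tissue-specific.
#'
#' @return List with elements `dcb_lung`, `dcb_breast`, `heterode_breast`
#'   (character vectors) and `annotation_counts` (named list of integers and
#'   fractions).
#' @export
#' @examples
#' sets <- example_biomarker_sets()
#' nrow(merge_biomarker_sets(
#'   list(lung = sets$dcb_lung, breast = sets$dcb_breast),
#'   sets$heterode_breast
#' ))
example_biomarker_sets <- function() {
  list(
    dcb_lung = c("SLC34A2", "GABRG1", "ROS1", "AGR2", "GNAT3", "SFTPA2",
                 "MUC5B", "SFTA3", "SMIM22", "CXCL17", "BPIFA1", "WFDC2"),
    dcb_breast = c("CSN1S1", "FABP7", "OPN1SW", "SCGB2A2", "LALBA",
                   "CASP14", "KLK5", "WFDC2"),
    heterode_breast = c("SCGB2A2", "CASP14", "FABP7", "CRABP2", "VGLL1",
                        "SERPINB5", "TFF1"),
    annotation_counts = list(
      n_annotated_genes = 57820L,
      n_undetected_noncancer = 39564L,
      lung_specific_fraction = 0.003,
      breast_specific_fraction = 0.002,
      n_lung_dcb_tissue_specific = 6L,
      n_breast_dcb_tissue_specific = 4L
    )
  )
}
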