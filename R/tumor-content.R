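#' Compute tumor content per sample and gene
#'
#' Tumor content is the product of the cfDNA-derived tumor fraction and the
#' gene's expression (RPM) in the matched tumor tissue: a per-gene,
#' per-patient measure of how much of that transcript the tumor sheds into
#' plasma. The plain `product` is used for detectability analyses; its log10
#' transform (floored, since log10(0) is undefined) is the heteroDE GLM
#' covariate. Non-cancer samples carry covariate value exactly 0: RNA
#' shedding from healthy tissue into blood is assumed negligible.
#'
#' @param data Tibble with one row per (sample, gene) and columns
#'   `sample_id`, `gene`, `group` (`"noncancer"`/`"cancer"`),
#'   `tumor_fraction` (in \[0, 1\]; may be `NA` for non-cancer) and
#'   `tissue_expression_rpm` (>= 0; may be `NA` for non-cancer).
#' @param floor Floor applied inside the log10 (default `1e-6` product
#'   units); recorded as an attribute of the output.
#'
#' @return The input with columns `product`, `log10_product` and `covariate`
#'   added (`covariate` equals `log10_product` for cancer samples and 0 for
#'   non-cancer samples).
#' @export
#' @examples
#' compute_tumor_content(tibble::tibble(
#'   sample_id = c("Ca1", "NC1"), gene = "G1", group = c("cancer", "noncancer"),
#'   tumor_fraction = c(0.01, NA), tissue_expression_rpm = c(10, NA)
#' ))
compute_tumor_content <- function(data, floor = 1e-6) {
  req <- c("sample_id", "gene", "group", "tumor_fraction", "tissue_expression_rpm")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort(paste0("`data` must contain columns: ", paste(req, collapse = ", ")))
  }
  if (floor <= 0) abort("`floor` must be positive.")
  is_cancer <- data$group == "cancer"
  tf <- data$tumor_fraction[is_cancer]
  ex <- data$tissue_expression_rpm[is_cancer]
  if (any(is.na(tf)) || any(tf < 0 | tf > 1)) {
    abort("`tumor_fraction` must lie in [0, 1] for every cancer sample.")
  }
  if (any(is.na(ex)) || any(ex < 0)) {
    abort("`tissue_expression_rpm` must be non-negative for every cancer sample.")
  }
  out <- data
  out$product <- ifelse(is_cancer, data$tumor_fraction * data$tissue_expression_rpm, 0)
  out$log10_product <- ifelse(is_cancer, log10(pmax(out$product, floor)), 0)
  out$covariate <- ifelse(is_cancer, out$log10_product, 0)
  attr(out, "floor") <- floor
  out
}
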