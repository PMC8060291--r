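#' Correct UMI sequences against a whitelist
#'
#' Applies the Hamming-distance-1 error-correction heuristic used when
#' collapsing PCR duplicates by unique molecular identifier (UMI): an observed
#' UMI matching the whitelist exactly is kept; one within Hamming distance 1
#' of exactly one whitelist entry is assigned to that entry; anything else
#' (distance > 1 to all entries, or distance 1 to two or more entries) is
#' discarded. `N` bases count as mismatches at every position, so low-quality
#' UMIs are discarded rather than rescued.
#'
#' @param observed Character vector of observed UMI sequences
#'   (alphabet A/C/G/T/N).
#' @param whitelist Character vector of expected UMI sequences, all the same
#'   length as the observed UMIs.
#'
#' @return Character vector of the same length as `observed`: the corrected
#'   UMI, or `NA` where the read should be discarded.
#' @export
#' @examples
#' correct_umi(c("ACGT", "ACGA", "ANGT"), whitelist = c("ACGT", "TTTT"))
correct_umi <- function(observed, whitelist) {
  if (!length(whitelist)) abort("`whitelist` must contain at least one UMI.")
  len <- unique(nchar(c(observed, whitelist)))
  if (length(len) != 1L) {
    abort("all observed and whitelist UMIs must have the same length.")
  }
  ok <- grepl("^[ACGTN]*$", c(observed, whitelist))
  if (!all(ok)) abort("UMIs may only contain A, C, G, T or N.")

  wl <- do.call(rbind, strsplit(whitelist, "", fixed = TRUE))
  vapply(observed, function(obs) {
    oc <- strsplit(obs, "", fixed = TRUE)[[1]]
    # N never matches, not even another N
    mism <- sweep(wl, 2, oc, FUN = "!=") | wl == "N" |
      matrix(oc == "N", nrow = nrow(wl), ncol = len, byrow = TRUE)
    d <- rowSums(mism)
    if (any(d == 0L)) return(whitelist[which(d == 0L)[1L]])
    hits <- which(d == 1L)
    if (length(hits) == 1L) whitelist[hits] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}
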