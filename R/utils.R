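# Internal helpers shared across modules.

ts_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "toascore_error")))
}

#' Normalize chromosome naming style
#'
#' Converts chromosome labels to a single style so that inputs from sources
#' using `"chr1"` and `"1"` conventions can be intersected safely. Mixed
#' styles within one vector are accepted; mixing across *inputs* is caught
#' downstream by [check_chrom_style()].
#'
#' @param x character vector of chromosome labels.
#' @param style `"plain"` (strip a leading `"chr"`) or `"chr"` (ensure the
#'   prefix).
#' @return character vector in the requested style.
#' @export
normalize_chrom <- function(x, style = c("plain", "chr")) {
  style <- match.arg(style)
  x <- as.character(x)
  bare <- sub("^chr", "", x)
  if (style == "plain") bare else paste0("chr", bare)
}

#' Check that two inputs share a chromosome naming style
#'
#' @param a,b character vectors of chromosome labels from two inputs.
#' @param what_a,what_b names used in the error message.
#' @return invisibly `TRUE`; errors if one input uses the `"chr"` prefix and
#'   the other does not (silent non-overlap is never acceptable).
#' @export
check_chrom_style <- function(a, b, what_a = "first input", what_b = "second input") {
  has_chr <- function(x) any(grepl("^chr", x))
  if (length(a) && length(b) && has_chr(a) != has_chr(b)) {
    ts_error(
      sprintf(
        "chromosome naming styles differ between %s ('%s') and %s ('%s'); normalize with normalize_chrom()",
        what_a, a[[1]], what_b, b[[1]]
      ),
      "toascore_format_error"
    )
  }
  invisible(TRUE)
}

# 0-based half-open intervals -> IRanges (1-based closed). A SNP at 1-based
# position p lies in [start, end) iff start <= p - 1 < end, i.e. the IRanges
# built here overlap the width-1 range at p.
iranges_from_bed <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

granges_from_bed <- function(chrom, start, end) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = iranges_from_bed(start, end))
}

snp_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = IRanges::IRanges(pos, pos))
}

# Format numerics for TSV output with round-trip fidelity.
tsv_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
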