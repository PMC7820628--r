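# Cross-tissue decomposition of chromatin-state segmentations and per-SNP
# annotation lookup.

#' Partition per-tissue chromatin states into disjoint cross-tissue segments
#'
#' For each state label independently, the per-tissue interval sets are
#' decomposed (via `GenomicRanges::disjoin`) into non-overlapping segments,
#' each annotated with the exact set of tissues carrying that state over the
#' segment. Segments are therefore tissue-specific, shared across all
#' tissues, or shared by a proper subset; base coverage per (state, tissue)
#' is conserved exactly.
#'
#' @param states a `state_maps` data.frame (see [read_state_maps()]).
#' @return data.frame of class `partitioned_segments` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `state`, `tissues` (list column of
#'   character vectors), `n_tissues`.
#' @export
partition_states <- function(states) {
  out <- lapply(split(seq_len(nrow(states)), states$state), function(idx) {
    sub <- states[idx, , drop = FALSE]
    gr <- granges_from_bed(sub$chrom, sub$start, sub$end)
    S4Vectors::mcols(gr)$tissue <- sub$tissue
    dj <- GenomicRanges::disjoin(gr)
    hits <- GenomicRanges::findOverlaps(dj, gr)
    members <- split(S4Vectors::mcols(gr)$tissue[S4Vectors::subjectHits(hits)],
                     factor(S4Vectors::queryHits(hits), levels = seq_along(dj)))
    members <- lapply(members, function(x) sort(unique(x)))
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(dj)),
      start = GenomicRanges::start(dj) - 1L,
      end = GenomicRanges::end(dj),
      state = sub$state[[1]],
      tissues = I(unname(members)),
      n_tissues = lengths(members),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, out)
  ord <- order(df$chrom, df$start, df$state)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("partitioned_segments", "data.frame")
  df
}

#' Resolve, per SNP, the annotations it overlaps and in which tissues
#'
#' Each variant (single-base, 1-based position) is intersected with the
#' partitioned chromatin segments and with coding-sequence records. A SNP in
#' a segment of state `a` carried by tissues `{t...}` yields one hit
#' `(a, {t...})`; a SNP inside CDS record(s) yields one `"CDS"` hit carrying
#' the gene id(s). States outside `included_states` are dropped (their PPA
#' later feeds the unclassified score). Different state labels may co-occur
#' at one position across tissues; every included hit is emitted.
#'
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos`
#'   (typically a `credible_sets` table).
#' @param partition a `partitioned_segments` data.frame from
#'   [partition_states()].
#' @param cds optional `cds_records` data.frame; `NULL` disables CDS hits.
#' @param included_states character vector of state labels to score; states
#'   absent from it are ignored.
#' @return data.frame of class `snp_hits` with columns `snp_id`, `annotation`,
#'   `tissues` (list column; empty for CDS), `gene_id` (list column; empty
#'   for chromatin hits).
#' @export
annotate_snps <- function(variants, partition, cds = NULL,
                          included_states = NULL) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(variants)))
  check_chrom_style(variants$chrom, partition$chrom, "variants", "state partition")
  if (!is.null(included_states)) {
    part <- partition[partition$state %in% included_states, , drop = FALSE]
  } else {
    part <- partition
  }
  uv <- variants[!duplicated(variants$snp_id), c("snp_id", "chrom", "pos")]
  snp_gr <- snp_granges(uv$chrom, uv$pos)

  rows <- list()
  if (nrow(part)) {
    seg_gr <- granges_from_bed(part$chrom, part$start, part$end)
    hits <- GenomicRanges::findOverlaps(snp_gr, seg_gr)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      rows$chromatin <- data.frame(
        snp_id = uv$snp_id[qi],
        annotation = part$state[si],
        tissues = I(part$tissues[si]),
        gene_id = I(replicate(length(qi), character(0), simplify = FALSE)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(cds) && nrow(cds)) {
    check_chrom_style(variants$chrom, cds$chrom, "variants", "CDS records")
    cds_gr <- granges_from_bed(cds$chrom, cds$start, cds$end)
    chits <- GenomicRanges::findOverlaps(snp_gr, cds_gr)
    if (length(chits)) {
      qi <- S4Vectors::queryHits(chits)
      genes <- split(cds$gene_id[S4Vectors::subjectHits(chits)], qi)
      genes <- lapply(genes, function(g) sort(unique(g)))
      qidx <- as.integer(names(genes))
      rows$cds <- data.frame(
        snp_id = uv$snp_id[qidx],
        annotation = "CDS",
        tissues = I(replicate(length(qidx), character(0), simplify = FALSE)),
        gene_id = I(unname(genes)),
        stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(snp_id = character(0), annotation = character(0),
               tissues = I(list()), gene_id = I(list()),
               stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("snp_hits", "data.frame")
  df
}
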