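# TPM normalization and expression specificity scores (ESS).

#' TPM-normalize a count matrix
#'
#' Corrects read counts for gene length and library depth: per sample,
#' `rate_g = count_g / length_kb_g` and `TPM_g = 1e6 * rate_g / sum(rate)`.
#' Every sample column of the result sums to 1e6.
#'
#' @param expr an `expression_data` object (see [read_expression()]) with a
#'   non-NULL `gene_length`, or a gene x sample count matrix if `gene_length`
#'   is supplied.
#' @param gene_length named numeric vector of gene lengths in bp (only when
#'   `expr` is a bare matrix).
#' @return gene x sample TPM matrix.
#' @export
tpm_normalize <- function(expr, gene_length = NULL) {
  if (inherits(expr, "expression_data")) {
    counts <- expr$counts
    gene_length <- expr$gene_length
  } else {
    counts <- expr
  }
  if (is.null(gene_length)) {
    ts_error("gene lengths are required for TPM normalization", "toascore_validation_error")
  }
  if (!all(rownames(counts) %in% names(gene_length))) {
    miss <- setdiff(rownames(counts), names(gene_length))
    ts_error(sprintf("gene length missing for: %s",
                     paste(utils::head(miss, 5), collapse = ", ")),
             "toascore_validation_error")
  }
  len_kb <- gene_length[rownames(counts)] / 1000
  rate <- counts / len_kb
  depth <- colSums(rate)
  if (any(depth == 0)) {
    ts_error(sprintf("sample(s) with all-zero counts: %s",
                     paste(colnames(counts)[depth == 0], collapse = ", ")),
             "toascore_validation_error")
  }
  sweep(rate, 2, depth, "/") * 1e6
}

#' Compute expression specificity scores (ESS)
#'
#' For gene g and tissue t, the ESS is the median TPM of g across the samples
#' of t divided by the sum of those per-tissue medians over all evaluated
#' tissues. Rows of expressed genes sum to 1; genes with zero median in every
#' tissue get an all-zero row and are flagged.
#'
#' @param tpm gene x sample TPM matrix.
#' @param sample_tissue named character vector mapping sample_id -> tissue.
#' @param tissues ordered character vector of tissues to evaluate; every
#'   tissue must have at least one sample.
#' @return gene x tissue matrix of class `ess_matrix`; attribute
#'   `zero_genes` lists genes with all-zero medians.
#' @export
compute_ess <- function(tpm, sample_tissue, tissues) {
  sample_tissue <- sample_tissue[colnames(tpm)]
  med <- vapply(tissues, function(t) {
    cols <- which(!is.na(sample_tissue) & sample_tissue == t)
    if (length(cols) == 0) {
      ts_error(sprintf("tissue '%s' has no samples", t), "toascore_validation_error")
    }
    apply(tpm[, cols, drop = FALSE], 1, stats::median)
  }, numeric(nrow(tpm)))
  if (nrow(tpm) == 1) med <- matrix(med, nrow = 1, dimnames = list(rownames(tpm), tissues))
  denom <- rowSums(med)
  ess <- med / ifelse(denom == 0, 1, denom)
  ess[denom == 0, ] <- 0
  rownames(ess) <- rownames(tpm)
  colnames(ess) <- tissues
  structure(ess, class = c("ess_matrix", class(ess)),
            zero_genes = rownames(tpm)[denom == 0])
}

#' One-step ESS from an expression bundle
#'
#' @param expr `expression_data` object.
#' @param tissues ordered tissues to evaluate; defaults to every tissue in
#'   the sample map.
#' @param already_tpm set `TRUE` when `counts` already holds TPM values
#'   (skips [tpm_normalize()]).
#' @return `ess_matrix` as from [compute_ess()].
#' @export
ess_from_expression <- function(expr, tissues = NULL, already_tpm = FALSE) {
  if (is.null(tissues)) tissues <- unique(unname(expr$sample_tissue))
  tpm <- if (already_tpm) expr$counts else tpm_normalize(expr)
  compute_ess(tpm, expr$sample_tissue, tissues)
}
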