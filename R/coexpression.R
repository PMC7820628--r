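# Nearest-gene assignment, rank-sum expression-similarity test with
# rank-matched nulls, and the pairwise-Spearman mean-squared-correlation
# co-expression test.

#' Filter and rank genes by mean expression
#'
#' Genes with TPM < `min_tpm` in more than `max_low_frac` of samples in
#' every evaluated tissue are excluded; the remaining genes are ranked by
#' their mean TPM across all samples (rank 1 = highest expression).
#'
#' @param tpm gene x sample TPM matrix.
#' @param sample_tissue named character vector mapping sample -> tissue.
#' @param min_tpm expression floor (default 0.1 TPM).
#' @param max_low_frac maximal tolerated fraction of low samples per tissue
#'   (default 0.5).
#' @return data.frame of class `gene_ranking`: `gene_id`, `mean_expr`,
#'   `rank` (a permutation of 1..G over the retained genes).
#' @export
gene_ranking <- function(tpm, sample_tissue, min_tpm = 0.1,
                         max_low_frac = 0.5) {
  sample_tissue <- sample_tissue[colnames(tpm)]
  tissues <- unique(unname(sample_tissue))
  ok_any <- rep(FALSE, nrow(tpm))
  for (t in tissues) {
    cols <- which(sample_tissue == t)
    low_frac <- rowMeans(tpm[, cols, drop = FALSE] < min_tpm)
    ok_any <- ok_any | (low_frac <= max_low_frac)
  }
  kept <- tpm[ok_any, , drop = FALSE]
  mean_expr <- rowMeans(kept)
  rk <- rank(-mean_expr, ties.method = "first")
  out <- data.frame(gene_id = rownames(kept), mean_expr = mean_expr,
                    rank = as.integer(rk), stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Assign the k-th nearest gene to each signal's index SNP
#'
#' Distance is measured from the index SNP to the gene's transcription start
#' site on the same chromosome; ties break by gene id. Signals whose
#' credible set carries a coding score at or above `coding_cutoff` are
#' excluded (their association is plausibly driven by the coding variant
#' itself, not a nearby regulatory target), as are signals with fewer than
#' k genes on their chromosome (with a warning).
#'
#' @param signals data.frame with columns `signal_id`, `chrom`, `pos`
#'   (index-SNP position) and `coding_score`.
#' @param gene_pos data.frame with columns `gene_id`, `chrom`, `tss`
#'   (1-based TSS position).
#' @param k which nearest gene (1, 2, or 3).
#' @param coding_cutoff cumulative coding PPA above which a signal is
#'   dropped (default 0.1; `Inf` disables the filter).
#' @return data.frame `signal_id`, `gene_id`, `distance`.
#' @export
nearest_genes <- function(signals, gene_pos, k = 1, coding_cutoff = 0.1) {
  check_chrom_style(signals$chrom, gene_pos$chrom, "signals", "gene positions")
  keep <- signals$coding_score < coding_cutoff
  dropped_snps <- character(0)
  out <- lapply(which(keep), function(i) {
    genes <- gene_pos[gene_pos$chrom == signals$chrom[i], , drop = FALSE]
    if (nrow(genes) < k) return(NULL)
    d <- abs(genes$tss - signals$pos[i])
    ord <- order(d, genes$gene_id)
    data.frame(signal_id = signals$signal_id[i],
               gene_id = genes$gene_id[ord[k]],
               distance = d[ord[k]], stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("%d signal(s) dropped: fewer than %d genes on their chromosome",
                    dropped, k))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- data.frame(signal_id = character(0),
                                      gene_id = character(0),
                                      distance = numeric(0))
  rownames(res) <- NULL
  res
}

# Sample one rank-matched null gene per query gene, without replacement
# within the permutation. Window is on the global (mean-expression) rank.
sample_matched_nulls <- function(gene_set, ranking, window = 100) {
  rank_of <- stats::setNames(ranking$rank, ranking$gene_id)
  drawn <- character(0)
  for (g in gene_set) {
    r <- rank_of[[g]]
    cand <- ranking$gene_id[abs(ranking$rank - r) <= window]
    cand <- setdiff(cand, c(g, drawn))
    if (!length(cand)) {
      ts_error(sprintf("gene '%s' has no eligible rank-matched null neighbor", g),
               "toascore_validation_error")
    }
    drawn <- c(drawn, if (length(cand) == 1) cand else sample(cand, 1))
  }
  drawn
}

#' Expression-similarity rank-sum test with rank-matched nulls
#'
#' Within each evaluated tissue, genes are ranked by their mean expression
#' in that tissue (rank 1 = highest) and the rank sum of the query set is
#' compared with null gene sets matched on global expression rank: each
#' null gene is drawn from the +/- `null_window` global-rank neighborhood of
#' its query gene, inside the +/- `bg_window` background. Small rank sums
#' mean the set is highly expressed, so the empirical p uses the lower tail
#' and the enrichment factor is `null mean / observed` (> 1 for sets more
#' highly expressed than their matched background).
#'
#' @param gene_set character vector of query genes (all must be in
#'   `ranking`).
#' @param ranking `gene_ranking` data.frame over the filtered gene universe.
#' @param tpm gene x sample TPM matrix (at least the ranked genes).
#' @param sample_tissue named character vector mapping sample -> tissue.
#' @param tissues tissues to evaluate; defaults to all in `sample_tissue`.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param null_window,bg_window global-rank windows for null sampling
#'   (default 100) and background eligibility (default 150; nulls drawn
#'   within the narrower window automatically respect it).
#' @return data.frame of class `coexpr_results`: per tissue, `observed`
#'   (rank sum), `null_mean`, `enrichment_factor`, `p_emp`, `n_perm`,
#'   `seed`.
#' @export
expression_similarity_test <- function(gene_set, ranking, tpm, sample_tissue,
                                       tissues = NULL, n_perm = 1000, seed,
                                       null_window = 100, bg_window = 150) {
  stopifnot(null_window <= bg_window)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% ranking$gene_id)) {
    ts_error("gene_set contains genes outside the ranked universe",
             "toascore_validation_error")
  }
  sample_tissue <- sample_tissue[colnames(tpm)]
  if (is.null(tissues)) tissues <- unique(unname(sample_tissue))
  kept <- tpm[ranking$gene_id, , drop = FALSE]
  withr::with_seed(seed, {
    null_sets <- replicate(n_perm,
                           sample_matched_nulls(gene_set, ranking, null_window),
                           simplify = FALSE)
    out <- lapply(tissues, function(t) {
      cols <- which(sample_tissue == t)
      tissue_rank <- rank(-rowMeans(kept[, cols, drop = FALSE]),
                          ties.method = "average")
      observed <- sum(tissue_rank[gene_set])
      null_draws <- vapply(null_sets, function(s) sum(tissue_rank[s]),
                           numeric(1))
      data.frame(
        tissue = t, statistic = "rank_sum", observed = observed,
        null_mean = mean(null_draws),
        enrichment_factor = mean(null_draws) / observed,
        p_emp = empirical_p(observed, null_draws, "le"),
        n_perm = n_perm, seed = seed, stringsAsFactors = FALSE
      )
    })
    res <- do.call(rbind, out)
    class(res) <- c("coexpr_results", "data.frame")
    res
  })
}

# Mean squared Spearman correlation over unordered gene pairs within one
# tissue's samples. Zero-variance genes are dropped (their correlation is
# undefined).
msr_stat <- function(expr_sub, warn = FALSE) {
  keep <- apply(expr_sub, 1, function(x) stats::sd(x) > 0)
  if (warn && any(!keep)) {
    warning(sprintf("dropping %d zero-variance gene(s) from msr", sum(!keep)))
  }
  expr_sub <- expr_sub[keep, , drop = FALSE]
  if (nrow(expr_sub) < 2) return(NA_real_)
  rho <- stats::cor(t(expr_sub), method = "spearman")
  mean(rho[upper.tri(rho)]^2)
}

#' Co-expression test via mean squared pairwise Spearman correlation
#'
#' For the query gene set, within each tissue, computes the mean over
#' unordered gene pairs of the squared Spearman correlation of expression
#' (msr), and compares it against msr values of equally sized random draws
#' from the pool of proximal genes (the nearest genes of the full signal
#' list). Large msr means the set is co-expressed (upper-tail empirical p).
#'
#' @param gene_set character vector, at least 2 genes.
#' @param tpm gene x sample TPM matrix.
#' @param sample_tissue named character vector mapping sample -> tissue.
#' @param proximal_pool character vector of candidate genes for null draws.
#' @param tissues tissues to evaluate; defaults to all in `sample_tissue`.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return data.frame of class `coexpr_results`: per tissue, `observed`
#'   (msr), `null_mean`, `enrichment_factor` (observed / null mean),
#'   `p_emp`, `n_perm`, `seed`.
#' @export
coexpression_msr_test <- function(gene_set, tpm, sample_tissue,
                                  proximal_pool, tissues = NULL,
                                  n_perm = 10000, seed) {
  gene_set <- unique(gene_set)
  if (length(gene_set) < 2) {
    ts_error("gene_set must contain at least 2 genes", "toascore_validation_error")
  }
  proximal_pool <- unique(proximal_pool)
  sample_tissue <- sample_tissue[colnames(tpm)]
  if (is.null(tissues)) tissues <- unique(unname(sample_tissue))
  withr::with_seed(seed, {
    null_sets <- replicate(n_perm,
                           sample(proximal_pool, length(gene_set)),
                           simplify = FALSE)
    out <- lapply(tissues, function(t) {
      cols <- which(sample_tissue == t)
      sub <- tpm[, cols, drop = FALSE]
      observed <- msr_stat(sub[gene_set, , drop = FALSE], warn = TRUE)
      null_draws <- vapply(null_sets, function(s)
        msr_stat(sub[s, , drop = FALSE]), numeric(1))
      null_draws <- null_draws[!is.na(null_draws)]
      data.frame(
        tissue = t, statistic = "msr", observed = observed,
        null_mean = mean(null_draws),
        enrichment_factor = observed / mean(null_draws),
        p_emp = empirical_p(observed, null_draws, "ge"),
        n_perm = n_perm, seed = seed, stringsAsFactors = FALSE
      )
    })
    res <- do.call(rbind, out)
    class(res) <- c("coexpr_results", "data.frame")
    res
  })
}
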