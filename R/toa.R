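# Tissue-of-action scoring: enrichment-derived weights, per-SNP tissue
# vectors, PPA partitioning into TOA profiles, SSD tissue specificity, and
# 99% credible-set construction.

#' Build an annotation weight table from log2 fold enrichments
#'
#' Weights are `2^log2FE` per (annotation, tissue). Coding sequence is a
#' single genome-wide annotation, so its weight is tissue-invariant.
#'
#' @param log2fe long data.frame with columns `annotation`, `tissue`,
#'   `log2fe`, or an annotation x tissue matrix of log2 fold enrichments.
#' @param cds_log2fe scalar log2 fold enrichment for coding sequence.
#' @param annotations,tissues the (annotation, tissue) grid that must be
#'   covered; defaults to everything present in `log2fe`.
#' @return list of class `weight_table`: `w` (annotation x tissue matrix of
#'   positive weights) and `cds` (positive scalar).
#' @export
weights_from_log2fe <- function(log2fe, cds_log2fe, annotations = NULL,
                                tissues = NULL) {
  if (is.matrix(log2fe)) {
    m <- log2fe
  } else {
    stopifnot(all(c("annotation", "tissue", "log2fe") %in% names(log2fe)))
    annos <- if (is.null(annotations)) unique(log2fe$annotation) else annotations
    tiss <- if (is.null(tissues)) unique(log2fe$tissue) else tissues
    m <- matrix(NA_real_, length(annos), length(tiss),
                dimnames = list(annos, tiss))
    idx <- cbind(match(log2fe$annotation, annos), match(log2fe$tissue, tiss))
    keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
    m[idx[keep, , drop = FALSE]] <- log2fe$log2fe[keep]
  }
  if (!is.null(annotations)) m <- m[annotations, , drop = FALSE]
  if (!is.null(tissues)) m <- m[, tissues, drop = FALSE]
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    pairs <- apply(miss, 1, function(ij)
      paste0("(", rownames(m)[ij[1]], ", ", colnames(m)[ij[2]], ")"))
    ts_error(sprintf("missing log2 fold enrichment for: %s",
                     paste(utils::head(pairs, 10), collapse = ", ")),
             "toascore_validation_error")
  }
  structure(list(w = 2^m, cds = 2^cds_log2fe), class = "weight_table")
}

#' Per-SNP tissue score vectors
#'
#' For each SNP j and annotation a, the tissue component is
#' `s_{j,a,t} = w_{a,t} * m(j,a,t) / sum_i m(j,a,i)`, where the mapping value
#' `m` is 1 for a chromatin-state overlap in tissue t (so a state shared by
#' k tissues splits each tissue's weight by k) and the gene's ESS value for
#' a coding-sequence overlap (ESS rows sum to 1 for expressed genes, so the
#' denominator is already normalized). The SNP vector is the sum over
#' annotations, `s_j = sum_a s_{j,a}`.
#'
#' A SNP overlapping CDS records of several genes uses the mean of their ESS
#' vectors. Genes absent from the ESS matrix contribute a zero vector (with
#' a warning collected once).
#'
#' @param snp_ids character vector of all SNPs to score (rows of the
#'   result); SNPs without hits get zero vectors.
#' @param hits `snp_hits` data.frame from [annotate_snps()].
#' @param weights `weight_table` from [weights_from_log2fe()].
#' @param ess `ess_matrix` from [compute_ess()] (needed only when CDS hits
#'   are present).
#' @param tissues ordered character vector of evaluated tissues.
#' @return list of class `snp_vectors`: `scores` (SNP x tissue matrix of
#'   s_j), `cds_scores` (SNP x tissue matrix of the CDS-only component),
#'   `total` (rowSums of `scores`).
#' @export
snp_tissue_vectors <- function(snp_ids, hits, weights, ess = NULL, tissues) {
  n <- length(snp_ids)
  S <- matrix(0, n, length(tissues), dimnames = list(snp_ids, tissues))
  S_cds <- S
  if (nrow(hits)) {
    unknown_genes <- character(0)
    row_of <- match(hits$snp_id, snp_ids)
    if (anyNA(row_of)) {
      ts_error("hits reference SNPs absent from 'snp_ids'", "toascore_validation_error")
    }
    for (k in seq_len(nrow(hits))) {
      a <- hits$annotation[[k]]
      i <- row_of[[k]]
      if (a == "CDS") {
        genes <- hits$gene_id[[k]]
        known <- intersect(genes, rownames(ess))
        unknown_genes <- c(unknown_genes, setdiff(genes, rownames(ess)))
        if (length(known)) {
          eps <- colMeans(ess[known, tissues, drop = FALSE]) * length(known) / length(genes)
          S_cds[i, ] <- S_cds[i, ] + weights$cds * eps
        }
      } else {
        tset <- hits$tissues[[k]]
        if (!a %in% rownames(weights$w)) {
          ts_error(sprintf("no weight for annotation '%s'", a),
                   "toascore_validation_error")
        }
        tset <- intersect(tissues, tset)
        if (length(tset)) {
          S[i, tset] <- S[i, tset] + weights$w[a, tset] / length(tset)
        }
      }
    }
    if (length(unknown_genes)) {
      warning(sprintf("no ESS for gene(s) %s; their CDS hits contribute nothing",
                      paste(unique(unknown_genes), collapse = ", ")))
    }
    S <- S + S_cds
  }
  structure(list(scores = S, cds_scores = S_cds, total = rowSums(S)),
            class = "snp_vectors")
}

#' Partition credible-set PPA into tissue-of-action scores
#'
#' For credible set c with SNPs J, the TOA score vector is
#' `tau_c = sum_{j in J} P_j * s_j / sum_t s_{j,t}`; SNPs whose vector is
#' all-zero (no included annotation in any tissue) contribute their whole
#' PPA to the unclassified score `U_c = sum_j P_j - sum_t tau_{c,t}`. The
#' partition is exact: `sum_t tau_t + U` equals the cumulative PPA.
#'
#' @param credible_sets `credible_sets` data.frame.
#' @param vectors `snp_vectors` from [snp_tissue_vectors()] covering every
#'   credible SNP.
#' @return data.frame of class `toa_profiles`: `signal_id`, one column per
#'   tissue, `unclassified`, `cumulative_ppa`, `max_ppa`, `n_snps`,
#'   `coding_score` (share-weighted cumulative PPA attributable to CDS
#'   hits), `ssd`. Attribute `tissues` records the tissue columns.
#' @export
compute_toa <- function(credible_sets, vectors) {
  tissues <- colnames(vectors$scores)
  idx <- match(credible_sets$snp_id, rownames(vectors$scores))
  if (anyNA(idx)) {
    ts_error("snp_tissue_vectors must cover every credible-set SNP",
             "toascore_validation_error")
  }
  total <- vectors$total[idx]
  share <- vectors$scores[idx, , drop = FALSE] /
    ifelse(total > 0, total, 1)
  share[total == 0, ] <- 0
  cds_share <- rowSums(vectors$cds_scores[idx, , drop = FALSE]) /
    ifelse(total > 0, total, 1)
  cds_share[total == 0] <- 0

  sid <- factor(credible_sets$signal_id, levels = unique(credible_sets$signal_id))
  ppa <- credible_sets$ppa
  tau <- rowsum(share * ppa, sid)
  cum_ppa <- rowsum(ppa, sid)[, 1]
  coding <- rowsum(cds_share * ppa, sid)[, 1]
  max_ppa <- tapply(ppa, sid, max)
  n_snps <- as.integer(table(sid))

  df <- data.frame(signal_id = levels(sid), stringsAsFactors = FALSE)
  for (t in tissues) df[[t]] <- tau[, t]
  df$unclassified <- cum_ppa - rowSums(tau)
  df$cumulative_ppa <- cum_ppa
  df$max_ppa <- as.numeric(max_ppa)
  df$n_snps <- n_snps
  df$coding_score <- coding
  df$ssd <- ssd_vec(tau)
  rownames(df) <- NULL
  class(df) <- c("toa_profiles", "data.frame")
  attr(df, "tissues") <- tissues
  df
}

#' End-to-end TOA scoring
#'
#' Convenience wrapper: annotate credible SNPs against a chromatin-state
#' partition (and optional CDS records), build per-SNP tissue vectors, and
#' partition PPA into per-signal TOA profiles.
#'
#' @inheritParams annotate_snps
#' @inheritParams snp_tissue_vectors
#' @param credible_sets `credible_sets` data.frame.
#' @return `toa_profiles` data.frame (see [compute_toa()]).
#' @export
toa_scores <- function(credible_sets, partition, weights, tissues,
                       cds = NULL, ess = NULL, included_states = NULL) {
  hits <- annotate_snps(credible_sets, partition, cds = cds,
                        included_states = included_states)
  vecs <- snp_tissue_vectors(unique(credible_sets$snp_id), hits, weights,
                             ess = ess, tissues = tissues)
  compute_toa(credible_sets, vecs)
}

#' Effect-size-weighted TOA scores
#'
#' Scales a signal's TOA vector by `|beta| / se` of its index SNP, giving
#' scores robust to differences in GWAS association strength.
#'
#' @param profiles `toa_profiles` data.frame.
#' @param beta,se named numeric vectors (by `signal_id`) of index-SNP effect
#'   sizes and standard errors (`se > 0`).
#' @return data.frame `signal_id` plus one `omega` column per tissue.
#' @export
weighted_toa <- function(profiles, beta, se) {
  tissues <- attr(profiles, "tissues")
  b <- beta[profiles$signal_id]
  s <- se[profiles$signal_id]
  if (anyNA(b) || anyNA(s)) {
    miss <- profiles$signal_id[is.na(b) | is.na(s)]
    ts_error(sprintf("missing beta/se for signal(s): %s",
                     paste(utils::head(miss, 5), collapse = ", ")),
             "toascore_validation_error")
  }
  if (any(s <= 0)) {
    ts_error("standard errors must be > 0", "toascore_validation_error")
  }
  out <- profiles[, "signal_id", drop = FALSE]
  for (t in tissues) out[[t]] <- profiles[[t]] * abs(b) / s
  class(out) <- c("weighted_toa_profiles", "data.frame")
  attr(out, "tissues") <- tissues
  out
}

# Sum of squared pairwise differences between tissue scores, per row.
ssd_vec <- function(tau) {
  tau <- as.matrix(tau)
  n <- ncol(tau)
  out <- numeric(nrow(tau))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      out <- out + (tau[, i] - tau[, j])^2
    }
  }
  out
}

#' Tissue specificity as the sum of squared pairwise TOA differences
#'
#' Computed over the tissue scores only (the unclassified score is
#' excluded); equal scores give 0, a single-tissue profile `(1,0,0,0)` gives
#' 3 with four tissues. Larger values mean more tissue-specific signals.
#'
#' @param profiles `toa_profiles` data.frame, or a numeric matrix/vector of
#'   tissue scores.
#' @return numeric vector, one SSD per profile.
#' @export
ssd <- function(profiles) {
  if (inherits(profiles, "toa_profiles")) {
    tau <- as.matrix(profiles[, attr(profiles, "tissues"), drop = FALSE])
  } else if (is.vector(profiles)) {
    tau <- matrix(profiles, nrow = 1)
  } else {
    tau <- as.matrix(profiles)
  }
  unname(ssd_vec(tau))
}

#' Construct a 99% credible set from per-SNP PPAs
#'
#' Ranks SNPs by descending PPA and retains the minimal prefix whose
#' cumulative PPA reaches 0.99. Ties in PPA are broken by lexicographic
#' snp_id so the construction is deterministic.
#'
#' @param snp_id character vector.
#' @param ppa numeric vector of posterior probabilities in \[0, 1\].
#' @param target cumulative PPA to reach (default 0.99).
#' @return data.frame `snp_id`, `ppa`, `cum_ppa` of retained SNPs, in
#'   retention order; attribute `reached` is `FALSE` when the total PPA is
#'   below `target` (all SNPs are then retained).
#' @export
build_credible_set_99 <- function(snp_id, ppa, target = 0.99) {
  stopifnot(length(snp_id) == length(ppa))
  if (any(ppa < 0 | ppa > 1)) {
    ts_error("PPA outside [0, 1]", "toascore_validation_error")
  }
  if (sum(ppa) > 1 + 1e-6) {
    ts_error("PPAs sum to more than 1", "toascore_validation_error")
  }
  ord <- order(-ppa, snp_id)
  cum <- cumsum(ppa[ord])
  reached <- any(cum >= target)
  k <- if (reached) which(cum >= target)[[1]] else length(ord)
  if (!reached) {
    warning(sprintf("total PPA %.4f < %.2f; retaining all SNPs", sum(ppa), target))
  }
  keep <- ord[seq_len(k)]
  structure(
    data.frame(snp_id = snp_id[keep], ppa = ppa[keep],
               cum_ppa = cum[seq_len(k)], stringsAsFactors = FALSE),
    reached = reached
  )
}

#' Per-signal differential of maximum credible-set PPA over a null scheme
#'
#' Used to compare fine-mapping resolution between annotation schemes: for
#' each signal, the maximum PPA under a scheme minus the maximum PPA under
#' the annotation-free null analysis.
#'
#' @param scheme_ppa,null_ppa named numeric vectors (by signal) of maximum
#'   99% credible-set PPAs.
#' @return named numeric vector of differentials (scheme - null).
#' @export
max_ppa_differential <- function(scheme_ppa, null_ppa) {
  if (!setequal(names(scheme_ppa), names(null_ppa))) {
    ts_error("scheme and null must cover the same signals", "toascore_validation_error")
  }
  scheme_ppa - null_ppa[names(scheme_ppa)]
}
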