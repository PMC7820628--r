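# Rule-based assignment of signals to tissues, the "shared" designation, and
# fine-mapping-resolution tiers for shared signals.

#' Classify signals to tissues from their TOA profiles
#'
#' A signal is assigned to the tissue with the maximum TOA score when that
#' score meets the stringency threshold; with `allow_shared`, a signal whose
#' top two scores differ by at most `share_gap` (default 0.10) is labeled
#' `"shared"` instead (provided the top score still meets the threshold).
#' Anything below threshold — including an all-zero profile at threshold
#' 0 — is `"unclassified"`.
#'
#' With `allow_shared = FALSE`, an exact tie for the maximum breaks by the
#' order of `tissue_order` (with a warning), keeping the classifier
#' deterministic.
#'
#' @param profiles `toa_profiles` data.frame.
#' @param threshold TOA stringency threshold; conventional values are 0.0,
#'   0.2, 0.5, 0.8.
#' @param allow_shared emit the `"shared"` label?
#' @param share_gap maximum difference between the top two scores for a
#'   shared call.
#' @param tissue_order tie-break order; defaults to the profile's tissue
#'   columns.
#' @return data.frame of class `toa_assignments`: `signal_id`, `label`
#'   (tissue, `"shared"`, or `"unclassified"`), `top_score`,
#'   `runner_up_gap`, `threshold`.
#' @export
classify_signals <- function(profiles, threshold = 0.2, allow_shared = TRUE,
                             share_gap = 0.10, tissue_order = NULL) {
  tissues <- attr(profiles, "tissues")
  if (is.null(tissue_order)) tissue_order <- tissues
  tau <- as.matrix(profiles[, tissues, drop = FALSE])
  # order columns by tie-break preference so max.col("first") is deterministic
  tau_ord <- tau[, tissue_order, drop = FALSE]
  top_idx <- max.col(tau_ord, ties.method = "first")
  top <- tau_ord[cbind(seq_len(nrow(tau_ord)), top_idx)]
  second <- vapply(seq_len(nrow(tau_ord)), function(i) {
    v <- tau_ord[i, -top_idx[i]]
    if (length(v)) max(v) else 0
  }, numeric(1))
  gap <- top - second

  label <- rep("unclassified", nrow(profiles))
  eligible <- top >= threshold & top > 0
  label[eligible] <- tissue_order[top_idx[eligible]]
  if (allow_shared) {
    label[eligible & gap <= share_gap] <- "shared"
  } else {
    tied <- eligible & gap == 0
    if (any(tied)) {
      warning(sprintf("%d signal(s) with exact top-score ties broken by tissue order",
                      sum(tied)))
    }
  }
  out <- data.frame(signal_id = profiles$signal_id, label = label,
                    top_score = top, runner_up_gap = gap,
                    threshold = threshold, stringsAsFactors = FALSE)
  class(out) <- c("toa_assignments", "data.frame")
  out
}

#' Tier shared signals by fine-mapping resolution
#'
#' Shared signals are tiered: (1) the credible set holds a single SNP;
#' (2) the maximum PPA is at least 0.50 (one SNP explains most of the
#' cumulative PPA); (3) the maximum PPA is below 0.50. Rules are tested in
#' order.
#'
#' @param profiles `toa_profiles` data.frame with `n_snps` and `max_ppa`.
#' @param assignments `toa_assignments` from [classify_signals()]; only
#'   signals labeled `"shared"` may be tiered.
#' @return data.frame `signal_id`, `tier` for the shared signals.
#' @export
tier_shared <- function(profiles, assignments) {
  shared_ids <- assignments$signal_id[assignments$label == "shared"]
  if (!length(shared_ids)) {
    ts_error("no signals labeled 'shared' to tier", "toascore_validation_error")
  }
  sub <- profiles[match(shared_ids, profiles$signal_id), , drop = FALSE]
  tier <- ifelse(sub$n_snps == 1L, 1L, ifelse(sub$max_ppa >= 0.50, 2L, 3L))
  data.frame(signal_id = shared_ids, tier = tier, stringsAsFactors = FALSE)
}
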