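# Permutation/resampling enrichment statistics: tissue-specific eQTL
# enrichment, physiology-cluster enrichment, GWAS-catalog overlap
# enrichment, and the shared empirical-p machinery.

#' Empirical p value with the add-one rule
#'
#' `p = (#{null draws at least/most as extreme as observed} + 1) / (N + 1)`;
#' the minimum attainable value is `1 / (N + 1)`, never 0.
#'
#' @param observed observed statistic.
#' @param null_draws numeric vector of null statistics.
#' @param tail `"ge"` counts nulls `>= observed`, `"le"` counts nulls
#'   `<= observed`.
#' @return empirical p value in `[1/(N+1), 1]`.
#' @export
empirical_p <- function(observed, null_draws, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  if (!length(null_draws)) {
    ts_error("null_draws is empty", "toascore_validation_error")
  }
  n <- if (tail == "ge") sum(null_draws >= observed) else sum(null_draws <= observed)
  (n + 1) / (length(null_draws) + 1)
}

#' Derive tissue-specific eQTL sets
#'
#' The tissue-specific set for tissue t is the set of its significant eQTLs
#' that are significant in no other evaluated tissue:
#' `specific(t) = S_t \ union of S_u, u != t`. Specific sets are pairwise
#' disjoint by construction.
#'
#' @param significant named list, tissue -> character vector of significant
#'   eQTL identifiers (SNP ids, or `"snp:gene"` pairs if that is the chosen
#'   unit).
#' @return list of class `eqtl_sets`: `significant` (as given, deduplicated)
#'   and `specific` (named list of tissue-specific subsets).
#' @export
tissue_specific_eqtls <- function(significant) {
  significant <- lapply(significant, unique)
  tissues <- names(significant)
  specific <- lapply(tissues, function(t) {
    others <- unlist(significant[setdiff(tissues, t)], use.names = FALSE)
    setdiff(significant[[t]], others)
  })
  names(specific) <- tissues
  structure(list(significant = significant, specific = specific),
            class = "eqtl_sets")
}

#' Benjamini-Hochberg filter for nominal eQTL p values
#'
#' Utility for users holding only nominal p values: returns the identifiers
#' passing a BH false-discovery-rate threshold. This approximates, but is
#' not identical to, a q-value procedure.
#'
#' @param ids character vector of eQTL identifiers.
#' @param p nominal p values, same length.
#' @param fdr threshold (default 0.05).
#' @return character vector of significant identifiers.
#' @export
filter_eqtls_fdr <- function(ids, p, fdr = 0.05) {
  stopifnot(length(ids) == length(p))
  ids[stats::p.adjust(p, method = "BH") <= fdr]
}

new_enrichment_result <- function(query_label, feature_label, observed,
                                  null_draws, tail, n_perm, seed) {
  null_mean <- mean(null_draws)
  # 0/0 is "nothing observed, nothing expected": no enrichment, not missing
  fold <- if (null_mean > 0) observed / null_mean else
    if (observed == 0) 0 else NA_real_
  data.frame(
    query_label = query_label, feature_label = feature_label,
    observed = observed, null_mean = null_mean, fold = fold,
    p_emp = empirical_p(observed, null_draws, tail),
    n_perm = n_perm, seed = seed, stringsAsFactors = FALSE
  )
}

#' Uniform matched-SNP sampler
#'
#' Default null sampler for [eqtl_enrichment()]: draws size-matched SNP sets
#' uniformly (without replacement) from a supplied universe. A stratified
#' sampler matching covariate bins can be built with
#' [stratified_snp_sampler()].
#'
#' @param universe character vector of candidate SNP ids.
#' @return function `(query_snps) -> character vector` of equally many
#'   sampled SNPs.
#' @export
uniform_snp_sampler <- function(universe) {
  universe <- unique(universe)
  function(query_snps) sample(universe, length(query_snps), replace = FALSE)
}

#' Stratified matched-SNP sampler
#'
#' Draws, for each query SNP, one SNP from the same covariate bin (e.g. MAF
#' decile), without replacement within a permutation.
#'
#' @param universe character vector of candidate SNP ids.
#' @param bins named vector (by SNP id) assigning each universe SNP to a bin.
#' @return function `(query_snps) -> character vector` of matched SNPs.
#' @export
stratified_snp_sampler <- function(universe, bins) {
  universe <- unique(universe)
  bins <- bins[universe]
  by_bin <- split(universe, bins)
  function(query_snps) {
    drawn <- character(0)
    for (s in query_snps) {
      pool <- setdiff(by_bin[[as.character(bins[[s]])]], c(drawn, s))
      if (!length(pool)) {
        ts_error(sprintf("no remaining matched SNPs in the bin of '%s'", s),
                 "toascore_validation_error")
      }
      drawn <- c(drawn, if (length(pool) == 1) pool else sample(pool, 1))
    }
    drawn
  }
}

#' Tissue-specific eQTL enrichment of tissue-assigned signals
#'
#' For every (assigned tissue, eQTL tissue) cell: the observed number of the
#' assigned index SNPs that are tissue-specific eQTLs, divided by the mean
#' overlap across permuted size-matched SNP sets; empirical p with the
#' upper tail.
#'
#' @param assigned_snps named list, assigned tissue -> character vector of
#'   index SNP ids for the signals assigned to that tissue.
#' @param eqtl_sets `eqtl_sets` from [tissue_specific_eqtls()].
#' @param sampler a function `(query_snps) -> matched snp ids` (e.g. from
#'   [uniform_snp_sampler()] or [stratified_snp_sampler()]).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed (mandatory; recorded in the output).
#' @return data.frame of `EnrichmentResult` rows, one per (assigned tissue,
#'   eQTL tissue) pair; `fold` is `NA` when the null mean is 0.
#' @export
eqtl_enrichment <- function(assigned_snps, eqtl_sets, sampler,
                            n_perm = 1000, seed) {
  withr::with_seed(seed, {
    out <- list()
    for (qt in names(assigned_snps)) {
      query <- unique(assigned_snps[[qt]])
      nulls <- replicate(n_perm, sampler(query), simplify = FALSE)
      for (ft in names(eqtl_sets$specific)) {
        spec <- eqtl_sets$specific[[ft]]
        observed <- sum(query %in% spec)
        null_draws <- vapply(nulls, function(s) sum(s %in% spec), numeric(1))
        out[[paste(qt, ft)]] <- new_enrichment_result(
          qt, ft, observed, null_draws, "ge", n_perm, seed)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("enrichment_results", "data.frame")
    res
  })
}

#' Physiology-cluster enrichment of tissue-assigned signals
#'
#' Null sets are drawn by sampling `|query|` signals without replacement
#' from the universe of fine-mapped signals; per cluster, the observed
#' overlap is compared with the null overlaps (upper tail).
#'
#' @param query_signals character vector of signal ids (e.g. one tissue's
#'   assignments), a subset of `universe`.
#' @param cluster_map named list, cluster -> character vector of signal ids.
#' @param universe character vector of all fine-mapped signal ids.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @param query_label label recorded in the results.
#' @return data.frame of `EnrichmentResult` rows, one per cluster.
#' @export
physiology_enrichment <- function(query_signals, cluster_map, universe,
                                  n_perm = 10000, seed,
                                  query_label = "query") {
  query_signals <- unique(query_signals)
  if (!all(query_signals %in% universe)) {
    ts_error("query signals must be a subset of the universe",
             "toascore_validation_error")
  }
  withr::with_seed(seed, {
    nulls <- replicate(n_perm, sample(universe, length(query_signals)),
                       simplify = FALSE)
    out <- lapply(names(cluster_map), function(cl) {
      members <- cluster_map[[cl]]
      observed <- sum(query_signals %in% members)
      null_draws <- vapply(nulls, function(s) sum(s %in% members), numeric(1))
      new_enrichment_result(query_label, cl, observed, null_draws, "ge",
                            n_perm, seed)
    })
    res <- do.call(rbind, out)
    class(res) <- c("enrichment_results", "data.frame")
    res
  })
}

#' GWAS-catalog trait enrichment with per-signal collapsed overlaps
#'
#' Each signal carries its index SNP plus LD proxies; any number of those
#' SNPs shared with a trait's SNP set counts as a single overlap for the
#' signal (guarding against local-LD inflation). Null sets resample signals
#' from the universe, each resampled signal expanding to its own proxies.
#'
#' @param signal_snps named list, signal id -> character vector of index +
#'   proxy SNP ids.
#' @param trait_snp_sets named list, trait -> character vector of
#'   trait-associated SNP ids; traits with empty sets are skipped with a
#'   warning.
#' @param query_signals character vector of signal ids to test (subset of
#'   `names(signal_snps)`).
#' @param universe character vector of signal ids to resample from; defaults
#'   to `names(signal_snps)`.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @param query_label label recorded in the results.
#' @return data.frame of `EnrichmentResult` rows, one per trait.
#' @export
gwascat_enrichment <- function(signal_snps, trait_snp_sets, query_signals,
                               universe = names(signal_snps),
                               n_perm = 10000, seed, query_label = "query") {
  query_signals <- unique(query_signals)
  stopifnot(all(query_signals %in% names(signal_snps)),
            all(universe %in% names(signal_snps)))
  count_overlap <- function(signals, trait_set) {
    sum(vapply(signal_snps[signals],
               function(s) any(s %in% trait_set), logical(1)))
  }
  withr::with_seed(seed, {
    nulls <- replicate(n_perm, sample(universe, length(query_signals)),
                       simplify = FALSE)
    out <- list()
    for (trait in names(trait_snp_sets)) {
      tset <- trait_snp_sets[[trait]]
      if (!length(tset)) {
        warning(sprintf("trait '%s' has an empty SNP set; skipped", trait))
        next
      }
      observed <- count_overlap(query_signals, tset)
      null_draws <- vapply(nulls, count_overlap, numeric(1), trait_set = tset)
      out[[trait]] <- new_enrichment_result(query_label, trait, observed,
                                            null_draws, "ge", n_perm, seed)
    }
    if (!length(out)) {
      out <- list(data.frame(
        query_label = character(0), feature_label = character(0),
        observed = numeric(0), null_mean = numeric(0), fold = numeric(0),
        p_emp = numeric(0), n_perm = integer(0), seed = integer(0)))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("enrichment_results", "data.frame")
    res
  })
}
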