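# Deterministic generator of toy genomes, chromatin-state maps, expression
# matrices, credible sets with planted tissues-of-action, and the companion
# eQTL/cluster/catalog tables, so every pipeline stage is testable offline.

#' Configuration for the synthetic fixture generator
#'
#' Defaults describe a compact but structurally faithful study: four
#' T2D-relevant tissues over a 1 Mb toy chromosome, enhancer-scale regulatory
#' elements (mean 600 bp) of which 30% are shared between tissues,
#' credible sets with a geometric size distribution (mean 20 SNPs), and a
#' tissue-skewed expression matrix with 20 samples per tissue.
#'
#' @param tissues evaluated tissue labels.
#' @param n_signals number of credible sets to plant.
#' @param genome_length toy chromosome length in bp.
#' @param active_states chromatin-state labels used for regulatory elements.
#' @param inactive_state label filling the rest of the genome.
#' @param fraction_shared probability an element is shared by >= 2 tissues.
#' @param mean_cs_size mean credible-set size (geometric; 1 gives single-SNP
#'   sets with PPA 1).
#' @param p_informative probability a credible SNP falls in an element
#'   active in the signal's planted tissue.
#' @param mean_element_length,mean_gap element geometry in bp.
#' @param n_genes,samples_per_tissue expression-panel dimensions.
#' @param state_log2fe log2 fold enrichment given to every active state in
#'   every tissue (the weight table of the fixture).
#' @param cds_log2fe log2 fold enrichment of coding sequence.
#' @param seed mandatory RNG seed; identical seeds give byte-identical
#'   bundles.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(tissues = c("islet", "adipose", "liver", "muscle"),
                           n_signals = 100,
                           genome_length = 1e6,
                           active_states = c("Active_TSS", "Strong_enhancer",
                                             "Weak_enhancer",
                                             "Strong_transcription",
                                             "Weak_transcription"),
                           inactive_state = "Quiescent_low_signal",
                           fraction_shared = 0.30,
                           mean_cs_size = 20,
                           p_informative = 0.8,
                           mean_element_length = 600,
                           mean_gap = 1000,
                           n_genes = 300,
                           samples_per_tissue = 20,
                           state_log2fe = 2,
                           cds_log2fe = 2.59,
                           seed) {
  if (missing(seed)) ts_error("a seed is mandatory", "toascore_validation_error")
  stopifnot(fraction_shared >= 0, fraction_shared <= 1,
            p_informative >= 0, p_informative <= 1,
            length(tissues) >= 2, mean_cs_size >= 1)
  if (fraction_shared >= 1 && mean_cs_size == 1 && p_informative == 1) {
    ts_error("infeasible config: all elements shared but distinct planted tissues requested",
             "toascore_validation_error")
  }
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate a synthetic fixture bundle
#'
#' Produces, deterministically from the seed: per-tissue chromatin-state
#' segmentations covering the toy genome; gene positions, CDS records,
#' gene lengths and a tissue-skewed count matrix; credible sets whose
#' high-PPA SNPs fall in elements active in each signal's planted tissue;
#' an annotation-by-tissue enrichment table; per-tissue significant-eQTL
#' lists; physiology-cluster, LD-proxy and trait-catalog tables; and a
#' ground-truth table (signal -> planted tissue) for recovery tests.
#'
#' @param cfg a [fixture_config()].
#' @return list of class `toa_fixture` holding every input object plus
#'   `truth` and the `config`.
#' @export
generate_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  withr::with_seed(cfg$seed, generate_fixture_impl(cfg))
}

generate_fixture_impl <- function(cfg) {
  tissues <- cfg$tissues
  nt <- length(tissues)

  ## --- regulatory elements along the toy chromosome -----------------------
  elements <- list()
  pos <- 0
  i <- 0
  repeat {
    gap <- round(stats::rexp(1, 1 / cfg$mean_gap))
    len <- max(100, round(stats::rexp(1, 1 / cfg$mean_element_length)))
    start <- pos + gap
    if (start + len > cfg$genome_length) break
    i <- i + 1
    shared <- stats::runif(1) < cfg$fraction_shared
    members <- if (shared && nt >= 2) {
      sort(sample(tissues, sample(2:nt, 1)))
    } else {
      sample(tissues, 1)
    }
    elements[[i]] <- list(start = start, end = start + len,
                          state = sample(cfg$active_states, 1),
                          members = members)
    pos <- start + len
  }
  el_start <- vapply(elements, `[[`, numeric(1), "start")
  el_end <- vapply(elements, `[[`, numeric(1), "end")
  el_state <- vapply(elements, `[[`, character(1), "state")
  el_members <- lapply(elements, `[[`, "members")

  state_maps <- do.call(rbind, lapply(tissues, function(t) {
    mine <- vapply(el_members, function(m) t %in% m, logical(1))
    act <- data.frame(chrom = "1", start = el_start[mine], end = el_end[mine],
                      state = el_state[mine], tissue = t,
                      stringsAsFactors = FALSE)
    act <- act[order(act$start), , drop = FALSE]
    # fill the remainder of the genome with the inactive state
    bounds <- c(0, as.vector(rbind(act$start, act$end)), cfg$genome_length)
    qs <- bounds[seq(1, length(bounds) - 1, by = 2)]
    qe <- bounds[seq(2, length(bounds), by = 2)]
    quiet <- data.frame(chrom = "1", start = qs[qs < qe], end = qe[qs < qe],
                        state = cfg$inactive_state, tissue = t,
                        stringsAsFactors = FALSE)
    out <- rbind(act, quiet)
    out[order(out$start), , drop = FALSE]
  }))
  state_maps <- validate_state_maps(state_maps)

  ## --- genes, CDS, expression ---------------------------------------------
  gene_ids <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  tss <- sort(sample(seq_len(cfg$genome_length - 200), cfg$n_genes))
  gene_pos <- data.frame(gene_id = gene_ids, chrom = "1", tss = tss,
                         stringsAsFactors = FALSE)
  cds <- data.frame(chrom = "1", start = tss - 1L, end = tss - 1L + 150L,
                    gene_id = gene_ids, stringsAsFactors = FALSE)
  class(cds) <- c("cds_records", "data.frame")

  gene_length <- stats::setNames(
    round(stats::runif(cfg$n_genes, 500, 5000)), gene_ids)
  sample_ids <- unlist(lapply(tissues, function(t)
    sprintf("%s_s%02d", t, seq_len(cfg$samples_per_tissue))))
  sample_tissue <- stats::setNames(rep(tissues, each = cfg$samples_per_tissue),
                                   sample_ids)
  # half the genes are skewed toward one tissue (8x baseline), cycling
  gene_tissue <- rep(c(tissues, NA), length.out = cfg$n_genes)
  base <- stats::rlnorm(cfg$n_genes, meanlog = 4, sdlog = 1)
  lambda <- outer(base, rep(1, length(sample_ids)))
  for (g in seq_len(cfg$n_genes)) {
    if (!is.na(gene_tissue[g])) {
      lambda[g, sample_tissue == gene_tissue[g]] <-
        lambda[g, sample_tissue == gene_tissue[g]] * 8
    }
  }
  counts <- matrix(stats::rpois(length(lambda), lambda),
                   nrow = cfg$n_genes,
                   dimnames = list(gene_ids, sample_ids))
  expression <- structure(
    list(counts = counts, gene_length = gene_length,
         sample_tissue = sample_tissue),
    class = "expression_data")

  ## --- credible sets with planted tissues ---------------------------------
  # planted SNPs model regulatory variants: keep them out of coding sequence
  # (a coding overlap would re-split the score by the gene's ESS vector)
  noncoding_in <- function(e) {
    p <- seq(el_start[e] + 1L, el_end[e])
    i <- findInterval(p, tss)
    p[!(i >= 1 & p - tss[pmax(i, 1L)] <= 149)]
  }
  planted <- tissues[((seq_len(cfg$n_signals) - 1) %% nt) + 1]
  sizes <- if (cfg$mean_cs_size <= 1) rep(1L, cfg$n_signals) else
    1L + stats::rgeom(cfg$n_signals, prob = 1 / cfg$mean_cs_size)
  cs_rows <- vector("list", cfg$n_signals)
  for (s in seq_len(cfg$n_signals)) {
    k <- sizes[[s]]
    ppa <- if (k == 1) 1 else {
      x <- stats::rgamma(k, shape = 1)
      x / sum(x)
    }
    ppa <- sort(ppa, decreasing = TRUE)
    host <- which(vapply(el_members, function(m) planted[s] %in% m, logical(1)))
    snp_pos <- integer(k)
    for (j in seq_len(k)) {
      if (stats::runif(1) < cfg$p_informative && length(host)) {
        cand <- integer(0)
        for (try in seq_len(length(host))) {
          e <- if (length(host) == 1) host else sample(host, 1)
          cand <- noncoding_in(e)
          if (length(cand)) break
        }
        snp_pos[j] <- if (length(cand) == 1) cand else sample(cand, 1)
      } else {
        snp_pos[j] <- sample(cfg$genome_length, 1)
      }
    }
    sid <- sprintf("signal_%03d", s)
    cs_rows[[s]] <- data.frame(
      signal_id = sid,
      locus = sprintf("LOC%03d", s),
      snp_id = sprintf("rs%03d_%02d", s, seq_len(k)),
      chrom = "1", pos = snp_pos, ppa = ppa,
      beta = round(stats::rnorm(1, 0.12, 0.03), 4),
      se = round(stats::runif(1, 0.01, 0.03), 4),
      is_index = seq_len(k) == 1L,
      stringsAsFactors = FALSE
    )
  }
  credible_sets <- validate_credible_sets(do.call(rbind, cs_rows))
  truth <- data.frame(signal_id = sprintf("signal_%03d", seq_len(cfg$n_signals)),
                      tissue = planted, n_snps = sizes,
                      stringsAsFactors = FALSE)
  index_snp <- stats::setNames(sprintf("rs%03d_01", seq_len(cfg$n_signals)),
                               truth$signal_id)

  ## --- enrichment table (weights input) ------------------------------------
  log2fe <- expand.grid(annotation = cfg$active_states, tissue = tissues,
                        stringsAsFactors = FALSE)
  log2fe$log2fe <- cfg$state_log2fe

  ## --- validation-table companions -----------------------------------------
  decoys <- sprintf("decoy_%03d", seq_len(200))
  eqtls <- lapply(tissues, function(t) {
    own <- index_snp[truth$tissue == t]
    own <- own[stats::runif(length(own)) < 0.7]
    unique(c(own, sample(decoys, 25)))
  })
  names(eqtls) <- tissues

  cluster_of <- c("insulin_secretion", "insulin_action", "lipid_metabolism",
                  "insulin_action")[match(truth$tissue, tissues)]
  clusters <- lapply(split(truth$signal_id, cluster_of), function(ids) {
    ids[stats::runif(length(ids)) < 0.6]
  })

  signal_snps <- lapply(truth$signal_id, function(sid)
    c(index_snp[[sid]], sprintf("prx_%s_%d", sid, 1:2)))
  names(signal_snps) <- truth$signal_id
  trait_sets <- lapply(tissues, function(t) {
    ids <- truth$signal_id[truth$tissue == t]
    ids <- ids[stats::runif(length(ids)) < 0.6]
    picked <- vapply(ids, function(sid) sample(signal_snps[[sid]], 1), character(1))
    unique(c(unname(picked), sample(decoys, 15)))
  })
  names(trait_sets) <- paste0("trait_", tissues)

  structure(
    list(credible_sets = credible_sets, state_maps = state_maps, cds = cds,
         expression = expression, gene_pos = gene_pos, log2fe = log2fe,
         eqtls = eqtls, clusters = clusters, signal_snps = signal_snps,
         trait_sets = trait_sets, index_snp = index_snp, truth = truth,
         config = cfg),
    class = "toa_fixture")
}

#' Write a fixture bundle to disk in the package's external formats
#'
#' @param fixture a `toa_fixture` from [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  wtsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- path
  }
  wtsv(fixture$credible_sets, "credible_sets.tsv")
  for (t in unique(fixture$state_maps$tissue)) {
    sub <- fixture$state_maps[fixture$state_maps$tissue == t,
                              c("chrom", "start", "end", "state")]
    wtsv(sub, sprintf("states_%s.bed", t))
  }
  wtsv(fixture$cds, "cds.bed")
  cnt <- data.frame(gene_id = rownames(fixture$expression$counts),
                    fixture$expression$counts, check.names = FALSE)
  wtsv(cnt, "expression_counts.tsv")
  wtsv(data.frame(sample_id = names(fixture$expression$sample_tissue),
                  tissue = unname(fixture$expression$sample_tissue)),
       "sample_map.tsv")
  wtsv(data.frame(gene_id = names(fixture$expression$gene_length),
                  length = unname(fixture$expression$gene_length)),
       "gene_lengths.tsv")
  wtsv(fixture$gene_pos, "gene_positions.tsv")
  wtsv(fixture$log2fe, "enrichment_log2fe.tsv")
  for (t in names(fixture$eqtls)) {
    wtsv(data.frame(eqtl_id = fixture$eqtls[[t]]), sprintf("eqtls_%s.tsv", t))
  }
  wtsv(data.frame(
    cluster = rep(names(fixture$clusters), lengths(fixture$clusters)),
    signal_id = unlist(fixture$clusters, use.names = FALSE)), "clusters.tsv")
  wtsv(data.frame(
    signal_id = rep(names(fixture$signal_snps), lengths(fixture$signal_snps)),
    snp_id = unlist(fixture$signal_snps, use.names = FALSE)), "proxies.tsv")
  wtsv(data.frame(
    trait = rep(names(fixture$trait_sets), lengths(fixture$trait_sets)),
    snp_id = unlist(fixture$trait_sets, use.names = FALSE)), "trait_snps.tsv")
  wtsv(fixture$truth, "truth.tsv")
  invisible(files)
}

#' Score a fixture end to end
#'
#' Runs ESS, weight construction, state partitioning and TOA scoring on a
#' fixture bundle with its own configuration (active states included,
#' inactive state routed to the unclassified score).
#'
#' @param fixture a `toa_fixture`.
#' @return `toa_profiles` data.frame.
#' @export
score_fixture <- function(fixture) {
  cfg <- fixture$config
  ess <- ess_from_expression(fixture$expression, tissues = cfg$tissues)
  weights <- weights_from_log2fe(fixture$log2fe, cds_log2fe = cfg$cds_log2fe,
                                 annotations = cfg$active_states,
                                 tissues = cfg$tissues)
  partition <- partition_states(fixture$state_maps)
  toa_scores(fixture$credible_sets, partition, weights, cfg$tissues,
             cds = fixture$cds, ess = ess,
             included_states = cfg$active_states)
}

#' Planted-tissue recovery rate of the classifier on a fixture
#'
#' @param fixture a `toa_fixture`.
#' @param threshold classifier threshold (default 0.2).
#' @param allow_shared passed to [classify_signals()].
#' @param profiles optionally, precomputed [score_fixture()] output.
#' @return fraction of signals whose assigned label equals the planted
#'   tissue.
#' @export
recovery_rate <- function(fixture, threshold = 0.2, allow_shared = TRUE,
                          profiles = NULL) {
  if (is.null(profiles)) profiles <- score_fixture(fixture)
  asn <- classify_signals(profiles, threshold = threshold,
                          allow_shared = allow_shared)
  truth <- fixture$truth$tissue[match(asn$signal_id, fixture$truth$signal_id)]
  mean(asn$label == truth)
}
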