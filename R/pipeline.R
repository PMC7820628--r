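# Composite pipeline wiring: simulate -> ess -> annotate -> toa -> classify
# -> enrichment/co-expression, driven by a config list or YAML file, with
# provenance headers on every artifact.

pipeline_stages <- c("simulate", "ess", "annotate", "toa", "classify",
                     "enrich-eqtl", "enrich-physiology", "enrich-gwascat",
                     "coexpress")

#' Read a pipeline configuration
#'
#' @param path YAML file with keys: `out_dir`, `seed`, `tissues`,
#'   `included_states`, `threshold`, `allow_shared`, `n_perm`, and either
#'   `simulate: true` (generate the default fixture) or the input paths
#'   (`credible_sets`, `state_maps` as a tissue->path map, `cds`,
#'   `expression_counts`, `sample_map`, `gene_lengths`, `log2fe`,
#'   `cds_log2fe`, `gene_positions`, plus optional eQTL/cluster/catalog
#'   tables).
#' @return config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) {
    ts_error("config must set an explicit seed", "toascore_validation_error")
  }
  cfg
}

stage_artifact <- function(out_dir, stage) {
  file.path(out_dir, paste0(stage, ".tsv"))
}

provenance_line <- function(cfg, stage) {
  sprintf("toascore %s | stage %s | seed %s",
          as.character(utils::packageVersion("toascore")), stage,
          as.character(cfg$seed))
}

write_stage_tsv <- function(df, cfg, stage) {
  path <- stage_artifact(cfg$out_dir, stage)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# ", provenance_line(cfg, stage)), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], tsv_num)
  flat <- vapply(df, is.list, logical(1))
  df[flat] <- lapply(df[flat], function(col)
    vapply(col, paste, character(1), collapse = ","))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

require_stage <- function(cfg, stage) {
  path <- stage_artifact(cfg$out_dir, stage)
  if (!file.exists(path)) {
    ts_error(sprintf("missing upstream artifact '%s'; run stage '%s' first",
                     path, stage),
             "toascore_pipeline_error")
  }
  path
}

#' Run the TOA pipeline
#'
#' Executes the requested stages in order, reading each stage's inputs from
#' the configured paths (or the simulated fixture) and writing one TSV per
#' stage into `cfg$out_dir` with a provenance comment line. Re-running with
#' an identical config reproduces identical files.
#'
#' @param cfg config list (see [read_run_config()]) or a YAML path.
#' @param stages ordered subset of
#'   `c("simulate", "ess", "annotate", "toa", "classify", "enrich-eqtl",
#'   "enrich-physiology", "enrich-gwascat", "coexpress")`; defaults to the
#'   stages the config provides inputs for.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "ess", "annotate",
                                         "toa", "classify")) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$tissues)) cfg$tissues <- c("islet", "adipose", "liver", "muscle")
  if (is.null(cfg$threshold)) cfg$threshold <- 0.2
  if (is.null(cfg$allow_shared)) cfg$allow_shared <- TRUE
  if (is.null(cfg$n_perm)) cfg$n_perm <- 1000
  artifacts <- list()

  fixture <- NULL
  if ("simulate" %in% stages || isTRUE(cfg$simulate)) {
    fixture <- generate_fixture(fixture_config(seed = cfg$seed,
                                               tissues = cfg$tissues))
    fix_dir <- file.path(cfg$out_dir, "fixture")
    write_fixture(fixture, fix_dir)
    artifacts$simulate <- fix_dir
    cfg$credible_sets <- file.path(fix_dir, "credible_sets.tsv")
    cfg$state_maps <- stats::setNames(
      file.path(fix_dir, sprintf("states_%s.bed", cfg$tissues)), cfg$tissues)
    cfg$cds <- file.path(fix_dir, "cds.bed")
    cfg$expression_counts <- file.path(fix_dir, "expression_counts.tsv")
    cfg$sample_map <- file.path(fix_dir, "sample_map.tsv")
    cfg$gene_lengths <- file.path(fix_dir, "gene_lengths.tsv")
    cfg$log2fe <- file.path(fix_dir, "enrichment_log2fe.tsv")
    if (is.null(cfg$cds_log2fe)) cfg$cds_log2fe <- fixture$config$cds_log2fe
    if (is.null(cfg$included_states)) {
      cfg$included_states <- fixture$config$active_states
    }
  }

  expr <- NULL
  ess <- NULL
  if ("ess" %in% stages) {
    expr <- read_expression(cfg$expression_counts, cfg$sample_map,
                            cfg$gene_lengths)
    ess <- ess_from_expression(expr, tissues = cfg$tissues,
                               already_tpm = isTRUE(cfg$already_tpm))
    artifacts$ess <- write_stage_tsv(
      data.frame(gene_id = rownames(ess), as.data.frame(unclass(ess)),
                 check.names = FALSE),
      cfg, "ess")
  }

  credible <- NULL
  hits <- NULL
  partition <- NULL
  if (any(c("annotate", "toa") %in% stages)) {
    credible <- read_credible_sets(cfg$credible_sets)
    states <- read_state_maps(cfg$state_maps)
    partition <- partition_states(states)
  }
  if ("annotate" %in% stages) {
    cds <- if (!is.null(cfg$cds)) read_cds(cfg$cds) else NULL
    hits <- annotate_snps(credible, partition, cds = cds,
                          included_states = cfg$included_states)
    flat <- data.frame(snp_id = hits$snp_id, annotation = hits$annotation,
                       tissues = vapply(hits$tissues, paste, character(1),
                                        collapse = ","),
                       gene_id = vapply(hits$gene_id, paste, character(1),
                                        collapse = ","))
    artifacts$annotate <- write_stage_tsv(flat, cfg, "annotate")
  }

  profiles <- NULL
  if ("toa" %in% stages) {
    if (is.null(hits)) {
      flat <- read_tsv_checked(require_stage(cfg, "annotate"))
      split_col <- function(x) lapply(strsplit(as.character(x), ","),
                                      function(v) v[nzchar(v) & !is.na(v)])
      hits <- data.frame(snp_id = as.character(flat$snp_id),
                         annotation = as.character(flat$annotation),
                         tissues = I(split_col(flat$tissues)),
                         gene_id = I(split_col(flat$gene_id)),
                         stringsAsFactors = FALSE)
    }
    if (is.null(ess)) {
      require_stage(cfg, "ess")
      ess_df <- read_tsv_checked(stage_artifact(cfg$out_dir, "ess"))
      ess <- as.matrix(ess_df[, -1, drop = FALSE])
      rownames(ess) <- ess_df[[1]]
    }
    lfe <- read_tsv_checked(cfg$log2fe)
    weights <- weights_from_log2fe(lfe, cds_log2fe = cfg$cds_log2fe,
                                   annotations = cfg$included_states,
                                   tissues = cfg$tissues)
    vecs <- snp_tissue_vectors(unique(credible$snp_id), hits, weights,
                               ess = ess, tissues = cfg$tissues)
    profiles <- compute_toa(credible, vecs)
    artifacts$toa <- stage_artifact(cfg$out_dir, "toa")
    write_toa_table(profiles, artifacts$toa,
                    provenance = provenance_line(cfg, "toa"))
  }

  if ("classify" %in% stages) {
    if (is.null(profiles)) {
      require_stage(cfg, "toa")
      profiles <- read_toa_table(stage_artifact(cfg$out_dir, "toa"),
                                 tissues = cfg$tissues)
    }
    asn <- classify_signals(profiles, threshold = cfg$threshold,
                            allow_shared = cfg$allow_shared)
    shared <- asn$signal_id[asn$label == "shared"]
    asn$tier <- NA_integer_
    if (length(shared)) {
      tiers <- tier_shared(profiles, asn)
      asn$tier[match(tiers$signal_id, asn$signal_id)] <- tiers$tier
    }
    artifacts$classify <- write_stage_tsv(asn, cfg, "classify")
  }

  needs_assignments <- c("enrich-eqtl", "enrich-physiology", "enrich-gwascat",
                         "coexpress")
  asn <- NULL
  if (any(needs_assignments %in% stages)) {
    require_stage(cfg, "classify")
    asn <- read_tsv_checked(stage_artifact(cfg$out_dir, "classify"))
    if (is.null(credible)) credible <- read_credible_sets(cfg$credible_sets)
    # index SNP = flagged row, else the top-PPA row of each signal
    idx_rows <- if ("is_index" %in% names(credible)) {
      credible[credible$is_index, , drop = FALSE]
    } else {
      credible[!duplicated(credible$signal_id), , drop = FALSE]
    }
    index_snp <- stats::setNames(idx_rows$snp_id, idx_rows$signal_id)
    assigned <- split(asn$signal_id, asn$label)
    assigned <- assigned[intersect(cfg$tissues, names(assigned))]
  }

  if ("enrich-eqtl" %in% stages) {
    if (is.null(fixture) && is.null(cfg$eqtls)) {
      ts_error("enrich-eqtl needs per-tissue eQTL tables ('eqtls' config key)",
               "toascore_pipeline_error")
    }
    sig <- if (!is.null(fixture)) fixture$eqtls else
      lapply(cfg$eqtls, function(p) read_tsv_checked(p)[[1]])
    sets <- tissue_specific_eqtls(sig)
    sampler <- uniform_snp_sampler(unname(index_snp))
    res <- eqtl_enrichment(lapply(assigned, function(ids) index_snp[ids]),
                           sets, sampler, n_perm = cfg$n_perm,
                           seed = cfg$seed)
    artifacts$`enrich-eqtl` <- write_stage_tsv(res, cfg, "enrich-eqtl")
  }

  if ("enrich-physiology" %in% stages) {
    clusters <- if (!is.null(fixture)) fixture$clusters else {
      cl <- read_tsv_checked(cfg$clusters)
      split(cl$signal_id, cl$cluster)
    }
    res <- do.call(rbind, lapply(names(assigned), function(t)
      physiology_enrichment(assigned[[t]], clusters,
                            universe = unique(credible$signal_id),
                            n_perm = cfg$n_perm, seed = cfg$seed,
                            query_label = t)))
    artifacts$`enrich-physiology` <- write_stage_tsv(res, cfg,
                                                     "enrich-physiology")
  }

  if ("enrich-gwascat" %in% stages) {
    signal_snps <- if (!is.null(fixture)) fixture$signal_snps else {
      px <- read_tsv_checked(cfg$proxies)
      split(px$snp_id, px$signal_id)
    }
    trait_sets <- if (!is.null(fixture)) fixture$trait_sets else {
      tr <- read_tsv_checked(cfg$trait_snps)
      split(tr$snp_id, tr$trait)
    }
    res <- do.call(rbind, lapply(names(assigned), function(t)
      gwascat_enrichment(signal_snps, trait_sets, assigned[[t]],
                         n_perm = cfg$n_perm, seed = cfg$seed,
                         query_label = t)))
    artifacts$`enrich-gwascat` <- write_stage_tsv(res, cfg, "enrich-gwascat")
  }

  if ("coexpress" %in% stages) {
    if (is.null(expr)) {
      expr <- read_expression(cfg$expression_counts, cfg$sample_map,
                              cfg$gene_lengths)
    }
    tpm <- if (isTRUE(cfg$already_tpm)) expr$counts else tpm_normalize(expr)
    ranking <- gene_ranking(tpm, expr$sample_tissue)
    gp <- if (!is.null(fixture)) fixture$gene_pos else
      read_tsv_checked(cfg$gene_positions)
    if (is.null(profiles)) {
      require_stage(cfg, "toa")
      profiles <- read_toa_table(stage_artifact(cfg$out_dir, "toa"),
                                 tissues = cfg$tissues)
    }
    sig <- merge(
      data.frame(signal_id = names(index_snp),
                 snp_id = unname(index_snp), stringsAsFactors = FALSE),
      credible[, c("signal_id", "snp_id", "chrom", "pos")],
      by = c("signal_id", "snp_id"))
    sig$coding_score <- profiles$coding_score[match(sig$signal_id,
                                                    profiles$signal_id)]
    ng <- nearest_genes(sig, gp, k = 1)
    res <- do.call(rbind, lapply(names(assigned), function(t) {
      genes <- ng$gene_id[ng$signal_id %in% assigned[[t]]]
      genes <- intersect(genes, ranking$gene_id)
      if (length(genes) < 2) return(NULL)
      r <- expression_similarity_test(genes, ranking, tpm,
                                      expr$sample_tissue,
                                      tissues = cfg$tissues,
                                      n_perm = cfg$n_perm, seed = cfg$seed)
      r$query_label <- t
      r
    }))
    artifacts$coexpress <- write_stage_tsv(res, cfg, "coexpress")
  }

  invisible(artifacts)
}
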