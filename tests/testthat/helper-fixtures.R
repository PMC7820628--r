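# Shared builders for small in-code fixtures.

TISSUES <- c("islet", "adipose", "liver", "muscle")

# A weight table with unit weights (log2FE = 0) unless overridden.
toy_weights <- function(states = c("Active_TSS", "Strong_enhancer"),
                        tissues = TISSUES, log2fe = 0, cds_log2fe = 0) {
  grid <- expand.grid(annotation = states, tissue = tissues,
                      stringsAsFactors = FALSE)
  grid$log2fe <- log2fe
  weights_from_log2fe(grid, cds_log2fe = cds_log2fe,
                      annotations = states, tissues = tissues)
}

toy_credible_sets <- function(df) {
  df$locus <- df$signal_id
  validate_credible_sets(df)
}

# Write a credible-set TSV and return its path.
write_cs_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# The two-tissue overlapping-enhancer toy from the partition examples:
# islet enhancer [0,100), liver enhancer [50,150).
toy_overlap_states <- function() {
  validate_state_maps(data.frame(
    chrom = "1",
    start = c(0L, 50L),
    end = c(100L, 150L),
    state = "Active_enhancer_1",
    tissue = c("islet", "liver"),
    stringsAsFactors = FALSE
  ))
}

# Independent per-base labeling oracle for partition_states: for one state
# label, returns for every base the sorted set of tissues covering it.
brute_force_membership <- function(states, state_label, chrom, max_bp) {
  sub <- states[states$state == state_label & states$chrom == chrom, ]
  lapply(seq_len(max_bp) - 1L, function(b) {
    sort(unique(sub$tissue[sub$start <= b & b < sub$end]))
  })
}

# Independent linear-scan oracle for annotate_snps (chromatin part): for a
# 1-based position, scan the raw per-tissue intervals.
scan_snp_states <- function(states, chrom, pos, included) {
  b <- pos - 1L
  sub <- states[states$chrom == chrom & states$start <= b & b < states$end, ]
  sub <- sub[sub$state %in% included, ]
  if (!nrow(sub)) return(list())
  out <- split(sub$tissue, sub$state)
  lapply(out, function(x) sort(unique(x)))
}

# Independent per-SNP/per-annotation enumeration of the TOA partition,
# written as plain loops over the hit table (the naive double loop).
brute_force_toa <- function(credible_sets, hits, weights, ess, tissues) {
  signals <- unique(credible_sets$signal_id)
  res <- matrix(0, length(signals), length(tissues) + 1,
                dimnames = list(signals, c(tissues, "unclassified")))
  for (sid in signals) {
    rows <- credible_sets[credible_sets$signal_id == sid, ]
    for (r in seq_len(nrow(rows))) {
      snp <- rows$snp_id[r]
      s <- setNames(numeric(length(tissues)), tissues)
      h <- hits[hits$snp_id == snp, ]
      if (nrow(h)) {
        for (k in seq_len(nrow(h))) {
          if (h$annotation[k] == "CDS") {
            genes <- h$gene_id[[k]]
            eps <- setNames(numeric(length(tissues)), tissues)
            for (g in genes) {
              if (g %in% rownames(ess)) eps <- eps + ess[g, tissues]
            }
            s <- s + weights$cds * eps / length(genes)
          } else {
            tset <- intersect(tissues, h$tissues[[k]])
            for (t in tset) {
              s[t] <- s[t] + weights$w[h$annotation[k], t] / length(tset)
            }
          }
        }
      }
      tot <- sum(s)
      if (tot > 0) {
        res[sid, tissues] <- res[sid, tissues] + rows$ppa[r] * s / tot
      } else {
        res[sid, "unclassified"] <- res[sid, "unclassified"] + rows$ppa[r]
      }
    }
  }
  res
}

# Exact tail probability over all equally likely k-subsets of a universe:
# P(overlap-statistic of a random subset satisfies tail vs observed).
enumerate_subset_tail <- function(universe, k, stat, observed,
                                  tail = c("ge", "le")) {
  tail <- match.arg(tail)
  combos <- combn(universe, k, simplify = FALSE)
  vals <- vapply(combos, stat, numeric(1))
  if (tail == "ge") mean(vals >= observed) else mean(vals <= observed)
}
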