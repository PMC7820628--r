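make_hit <- function(snp_id, annotation, tissues = character(0),
                     gene_id = character(0)) {
  data.frame(snp_id = snp_id, annotation = annotation,
             tissues = I(list(tissues)), gene_id = I(list(gene_id)),
             stringsAsFactors = FALSE)
}

test_that("weights exponentiate log2 fold enrichments base 2", {
  w <- toy_weights(states = c("a1", "a2"), log2fe = c(0, -1, 2.84, 0, 0, 0, 0, 0))
  expect_equal(w$w["a1", "islet"], 1)       # log2FE 0
  expect_equal(w$w["a2", "islet"], 0.5)     # log2FE -1
  expect_equal(w$w["a1", "adipose"], 2^2.84, tolerance = 1e-12)
  expect_equal(2^2.84, 7.16, tolerance = 1e-3)  # the islet type-1 enhancer case
  expect_equal(toy_weights(cds_log2fe = 2.59)$cds, 2^2.59)

  grid <- expand.grid(annotation = "a1", tissue = c("islet", "liver"),
                      stringsAsFactors = FALSE)
  grid$log2fe <- 1
  expect_error(
    weights_from_log2fe(grid, cds_log2fe = 0, annotations = "a1",
                        tissues = TISSUES),
    "missing log2 fold enrichment")
})

test_that("per-SNP vectors split shared-state weights and spread CDS weight by ESS", {
  w <- weights_from_log2fe(
    rbind(data.frame(annotation = "enh", tissue = TISSUES, log2fe = c(1, 0, 0, 0)),
          data.frame(annotation = "enh2", tissue = TISSUES, log2fe = c(2, 0, 1, 0))),
    cds_log2fe = log2(6))
  ess <- matrix(c(0.6, 0.3, 0.1, 0), 1, dimnames = list("G", TISSUES))

  # islet-only hit with w = 2
  v1 <- snp_tissue_vectors("s1", make_hit("s1", "enh", "islet"), w, tissues = TISSUES)
  expect_equal(unname(v1$scores["s1", ]), c(2, 0, 0, 0))

  # enhancer shared by islet and muscle with w_islet = 4, w_muscle = 2:
  # each tissue weight is divided by the 2-tissue denominator
  w2 <- weights_from_log2fe(
    data.frame(annotation = "enh2", tissue = TISSUES, log2fe = c(2, 0, 0, 1)),
    cds_log2fe = 0)
  v2 <- snp_tissue_vectors("s1", make_hit("s1", "enh2", c("islet", "muscle")),
                           w2, tissues = TISSUES)
  expect_equal(unname(v2$scores["s1", ]), c(2, 0, 0, 1))

  # CDS hit with w_CDS = 6 and ESS (0.6, 0.3, 0.1, 0)
  v3 <- snp_tissue_vectors("s1", make_hit("s1", "CDS", gene_id = "G"),
                           w, ess = ess, tissues = TISSUES)
  expect_equal(unname(v3$scores["s1", ]), c(3.6, 1.8, 0.6, 0), tolerance = 1e-12)
  expect_equal(unname(v3$cds_scores["s1", ]), c(3.6, 1.8, 0.6, 0), tolerance = 1e-12)

  expect_error(
    snp_tissue_vectors("s1", make_hit("s1", "unknown_state", "islet"), w,
                       tissues = TISSUES),
    "no weight")
})

test_that("TOA partitioning allocates PPA by tissue shares and routes no-hit SNPs to unclassified", {
  w <- toy_weights(states = "enh", log2fe = 1)
  cs <- toy_credible_sets(data.frame(
    signal_id = c("s", "s"), snp_id = c("rs1", "rs2"), chrom = "1",
    pos = c(10L, 20L), ppa = c(0.6, 0.4)))
  hits <- make_hit("rs1", "enh", "islet")
  vecs <- snp_tissue_vectors(c("rs1", "rs2"), hits, w, tissues = TISSUES)
  p <- compute_toa(cs, vecs)
  expect_equal(p$islet, 0.6)
  expect_equal(p$unclassified, 0.4)
  expect_equal(p$cumulative_ppa, 1.0)
  expect_equal(p$n_snps, 2L)

  # single SNP, PPA 1, islet-only hit
  cs1 <- toy_credible_sets(data.frame(signal_id = "t", snp_id = "rs9",
                                      chrom = "1", pos = 5L, ppa = 1.0))
  v1 <- snp_tissue_vectors("rs9", make_hit("rs9", "enh", "islet"), w,
                           tissues = TISSUES)
  p1 <- compute_toa(cs1, v1)
  expect_equal(unname(unlist(p1[, TISSUES])), c(1, 0, 0, 0))
  expect_equal(p1$unclassified, 0)
})

test_that("TOA scoring equals the naive per-SNP/per-annotation enumeration on a random fixture", {
  fx <- generate_fixture(fixture_config(seed = 6, n_signals = 12,
                                        mean_cs_size = 5))
  ess <- ess_from_expression(fx$expression, tissues = TISSUES)
  w <- weights_from_log2fe(fx$log2fe, cds_log2fe = fx$config$cds_log2fe)
  seg <- partition_states(fx$state_maps)
  hits <- annotate_snps(fx$credible_sets, seg, cds = fx$cds,
                        included_states = fx$config$active_states)
  vecs <- snp_tissue_vectors(unique(fx$credible_sets$snp_id), hits, w,
                             ess = ess, tissues = TISSUES)
  p <- compute_toa(fx$credible_sets, vecs)
  oracle <- brute_force_toa(fx$credible_sets, hits, w, ess, TISSUES)
  got <- as.matrix(p[, c(TISSUES, "unclassified")])
  rownames(got) <- p$signal_id
  expect_equal(got, oracle[rownames(got), ], tolerance = 1e-12)
})

test_that("conservation, weight-scale invariance and weight monotonicity hold", {
  fx <- generate_fixture(fixture_config(seed = 7, n_signals = 20,
                                        mean_cs_size = 8))
  ess <- ess_from_expression(fx$expression, tissues = TISSUES)
  seg <- partition_states(fx$state_maps)
  hits <- annotate_snps(fx$credible_sets, seg, cds = fx$cds,
                        included_states = fx$config$active_states)
  score_with <- function(w) {
    vecs <- snp_tissue_vectors(unique(fx$credible_sets$snp_id), hits, w,
                               ess = ess, tissues = TISSUES)
    compute_toa(fx$credible_sets, vecs)
  }
  w <- weights_from_log2fe(fx$log2fe, cds_log2fe = fx$config$cds_log2fe)
  base <- score_with(w)
  expect_equal(rowSums(base[, c(TISSUES, "unclassified")]),
               base$cumulative_ppa, tolerance = 1e-9)

  for (k in c(0.1, 10)) {
    scaled <- w
    scaled$w <- scaled$w * k
    scaled$cds <- scaled$cds * k
    expect_equal(as.matrix(score_with(scaled)[, TISSUES]),
                 as.matrix(base[, TISSUES]), tolerance = 1e-12)
  }

  up <- w
  up$w[, "liver"] <- up$w[, "liver"] * 3
  expect_true(all(score_with(up)$liver >= base$liver - 1e-12))
})

test_that("with a single evaluated tissue, tau equals the annotated cumulative PPA", {
  states <- validate_state_maps(data.frame(
    chrom = "1", start = 0L, end = 100L, state = "enh", tissue = "islet"))
  w <- weights_from_log2fe(
    data.frame(annotation = "enh", tissue = "islet", log2fe = 1.7),
    cds_log2fe = 0)
  cs <- toy_credible_sets(data.frame(
    signal_id = "s", snp_id = c("in1", "in2", "out"), chrom = "1",
    pos = c(10L, 90L, 500L), ppa = c(0.5, 0.3, 0.2)))
  p <- toa_scores(cs, partition_states(states), w, tissues = "islet")
  expect_equal(p$islet, 0.8)
  expect_equal(p$unclassified, 0.2)
})

test_that("effect-size weighting scales TOA by |beta|/se", {
  profiles <- data.frame(signal_id = "s", islet = 0.5, adipose = 0.2,
                         liver = 0, muscle = 0, unclassified = 0.3)
  class(profiles) <- c("toa_profiles", "data.frame")
  attr(profiles, "tissues") <- TISSUES
  w1 <- weighted_toa(profiles, beta = c(s = 0.1), se = c(s = 0.05))
  expect_equal(w1$islet, 1.0)
  expect_equal(weighted_toa(profiles, c(s = 0), c(s = 0.05))$islet, 0)
  w2 <- weighted_toa(profiles, c(s = 0.1), se = c(s = 0.1))
  expect_equal(w2$islet, w1$islet / 2)
  expect_error(weighted_toa(profiles, c(other = 1), c(other = 1)),
               "missing beta/se")
  expect_error(weighted_toa(profiles, c(s = 1), c(s = 0)), "must be > 0")
})

test_that("SSD enumerates squared differences over unordered tissue pairs", {
  expect_equal(ssd(c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(ssd(c(1, 0, 0, 0)), 3)
  expect_equal(ssd(c(0.5, 0.5, 0, 0)), 1)
  # random check against direct pair enumeration
  set.seed(8)
  tau <- runif(4)
  pairs <- combn(4, 2)
  expect_equal(ssd(tau),
               sum((tau[pairs[1, ]] - tau[pairs[2, ]])^2))
})

test_that("99% credible-set construction keeps the minimal descending-PPA prefix", {
  r <- build_credible_set_99(c("a", "b", "c", "d"), c(0.7, 0.25, 0.04, 0.01))
  expect_equal(r$snp_id, c("a", "b", "c"))
  expect_equal(r$cum_ppa[3], 0.99)
  expect_equal(build_credible_set_99("only", 1.0)$snp_id, "only")
  expect_equal(nrow(build_credible_set_99(c("a", "b"), c(0.5, 0.5))), 2)
  # deterministic tie-break by snp_id
  tie <- build_credible_set_99(c("z", "y"), c(0.5, 0.5))
  expect_equal(tie$snp_id, c("y", "z"))
  expect_warning(r2 <- build_credible_set_99(c("a", "b"), c(0.5, 0.3)),
                 "retaining all")
  expect_false(attr(r2, "reached"))
  expect_equal(nrow(r2), 2)
})

test_that("max-PPA differentials subtract the null baseline per signal", {
  expect_equal(unname(max_ppa_differential(c(s1 = 0.8), c(s1 = 0.5))), 0.3)
  x <- c(a = 0.4, b = 0.9)
  expect_equal(max_ppa_differential(x, x), c(a = 0, b = 0))
  set.seed(9)
  scheme <- setNames(runif(10), paste0("s", 1:10))
  null <- setNames(runif(10), paste0("s", 1:10))
  expect_equal(max_ppa_differential(scheme, null), scheme - null)
  expect_error(max_ppa_differential(c(a = 1), c(b = 1)), "same signals")
})
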