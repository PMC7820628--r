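# Expression panel helper: n genes x (2 samples per tissue), with means
# chosen per gene and tissue.
panel_tpm <- function(means, tissues = TISSUES, reps = 2) {
  samples <- unlist(lapply(tissues, function(t) paste0(t, "_", seq_len(reps))))
  tpm <- matrix(0, nrow(means), length(samples),
                dimnames = list(rownames(means), samples))
  for (t in tissues) {
    cols <- grep(paste0("^", t, "_"), samples)
    for (j in cols) tpm[, j] <- means[, t]
  }
  tpm
}

sample_tissue_of <- function(tpm) {
  setNames(sub("_[0-9]+$", "", colnames(tpm)), colnames(tpm))
}

test_that("gene ranking filters low-expressed genes and ranks the rest", {
  means <- rbind(hi = c(100, 100, 100, 100), mid = c(10, 10, 10, 10),
                 lowall = c(0.01, 0.01, 0.01, 0.01),
                 isletonly = c(50, 0.01, 0.01, 0.01))
  colnames(means) <- TISSUES
  tpm <- panel_tpm(means)
  r <- gene_ranking(tpm, sample_tissue_of(tpm))
  expect_false("lowall" %in% r$gene_id)       # low in every tissue
  expect_true("isletonly" %in% r$gene_id)     # expressed in one tissue
  expect_setequal(r$rank, seq_len(nrow(r)))
  expect_equal(r$gene_id[r$rank == 1], "hi")
})

test_that("nearest-gene assignment picks the k-th closest TSS and applies the coding filter", {
  genes <- data.frame(gene_id = c("near", "far"), chrom = "1",
                      tss = c(90L, 200L))
  sig <- data.frame(signal_id = c("s1", "s2"), chrom = "1",
                    pos = c(100L, 100L), coding_score = c(0, 0.15))
  n1 <- nearest_genes(sig, genes, k = 1)
  expect_equal(n1$signal_id, "s1")          # s2 excluded: coding 0.15 >= 0.1
  expect_equal(n1$gene_id, "near")
  n2 <- nearest_genes(sig, genes, k = 2)
  expect_equal(n2$gene_id, "far")
  expect_warning(n3 <- nearest_genes(sig, genes, k = 3), "fewer than 3")
  expect_equal(nrow(n3), 0)
})

test_that("matched null genes always lie inside the rank window", {
  ranking <- data.frame(gene_id = paste0("g", 1:60), mean_expr = 60:1,
                        rank = 1:60)
  withr::with_seed(20, {
    for (i in 1:50) {
      drawn <- toascore:::sample_matched_nulls(c("g5", "g30", "g55"),
                                               ranking, window = 10)
      expect_equal(anyDuplicated(drawn), 0L)
      expect_true(all(abs(ranking$rank[match(drawn, ranking$gene_id)] -
                            c(5, 30, 55)) <= 10))
    }
  })
  tiny <- data.frame(gene_id = "g1", mean_expr = 1, rank = 1L)
  expect_error(toascore:::sample_matched_nulls("g1", tiny, window = 0),
               "no eligible")
})

test_that("a tissue's top-expressed set is detected; flat expression gives factor 1", {
  set.seed(21)
  n <- 40
  means <- matrix(10 + runif(n * 4), n, 4,
                  dimnames = list(paste0("g", 1:n), TISSUES))
  hot <- paste0("g", c(3, 17, 29))
  means[hot, "islet"] <- 1000    # islet-hot, but global rank barely moves
  tpm <- panel_tpm(means)
  st <- sample_tissue_of(tpm)
  ranking <- gene_ranking(tpm, st)
  res <- expression_similarity_test(hot, ranking, tpm, st,
                                    tissues = "islet", n_perm = 200, seed = 22)
  expect_equal(res$p_emp, 1 / 201)
  expect_gt(res$enrichment_factor, 1)

  flat <- panel_tpm(matrix(5, n, 4, dimnames = list(paste0("g", 1:n), TISSUES)))
  ranking_flat <- gene_ranking(flat, st)
  res_flat <- expression_similarity_test(paste0("g", 1:3), ranking_flat,
                                         flat, st, tissues = "islet",
                                         n_perm = 50, seed = 23)
  expect_equal(res_flat$enrichment_factor, 1)
})

test_that("similarity-test p matches exhaustive enumeration of null draws on a toy universe", {
  n <- 10
  means <- matrix(0, n, 4, dimnames = list(paste0("g", 1:n), TISSUES))
  means[, "islet"] <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  means[, "adipose"] <- seq(0.5, 5, length.out = n)  # fixes global ranks
  tpm <- panel_tpm(means)
  st <- sample_tissue_of(tpm)
  ranking <- gene_ranking(tpm, st)
  gene_set <- c("g2", "g5")
  res <- expression_similarity_test(gene_set, ranking, tpm, st,
                                    tissues = "islet", n_perm = 3000,
                                    seed = 24, null_window = 100)
  # exact law of the sequential without-replacement per-gene draw
  islet_rank <- rank(-means[, "islet"])
  observed <- sum(islet_rank[gene_set])
  genes <- rownames(means)
  prob_le <- 0
  cand1 <- setdiff(genes, "g2")
  for (a in cand1) {
    cand2 <- setdiff(genes, c("g5", a))
    for (b in cand2) {
      p_ab <- (1 / length(cand1)) * (1 / length(cand2))
      if (islet_rank[a] + islet_rank[b] <= observed) prob_le <- prob_le + p_ab
    }
  }
  expect_equal(res$p_emp, prob_le, tolerance = 0.03)
})

test_that("msr equals hand-computed mean squared Spearman correlations", {
  set.seed(25)
  expr <- matrix(rnorm(3 * 8), 3, 8,
                 dimnames = list(c("a", "b", "c"), paste0("islet_", 1:8)))
  expr["b", ] <- expr["a", ] * 2 + 1    # identical profile up to monotone map
  st <- sample_tissue_of(expr)
  res <- coexpression_msr_test(c("a", "b"), expr, st,
                               proximal_pool = c("a", "b", "c"),
                               tissues = "islet", n_perm = 50, seed = 26)
  expect_equal(res$observed, 1)          # rho = 1 exactly

  rho <- cor(t(expr), method = "spearman")
  hand <- mean(c(rho["a", "b"]^2, rho["a", "c"]^2, rho["b", "c"]^2))
  res3 <- coexpression_msr_test(c("a", "b", "c"), expr, st,
                                proximal_pool = c("a", "b", "c"),
                                tissues = "islet", n_perm = 50, seed = 26)
  expect_equal(res3$observed, hand, tolerance = 1e-12)

  # invariance under a monotone transformation of expression
  res_exp <- coexpression_msr_test(c("a", "b", "c"), exp(expr), st,
                                   proximal_pool = c("a", "b", "c"),
                                   tissues = "islet", n_perm = 50, seed = 26)
  expect_equal(res_exp$observed, res3$observed, tolerance = 1e-12)
})

test_that("white-noise gene sets are not called co-expressed", {
  set.seed(27)
  expr <- matrix(rnorm(30 * 20), 30, 20,
                 dimnames = list(paste0("g", 1:30), paste0("islet_", 1:20)))
  st <- sample_tissue_of(expr)
  res <- coexpression_msr_test(paste0("g", 1:4), expr, st,
                               proximal_pool = paste0("g", 1:30),
                               tissues = "islet", n_perm = 500, seed = 28)
  expect_gt(res$p_emp, 0.05)
  expect_true(res$observed >= 0 && res$observed <= 1)

  flatline <- expr
  flatline["g1", ] <- 3
  expect_warning(
    coexpression_msr_test(paste0("g", 1:3), flatline, st,
                          proximal_pool = paste0("g", 1:30),
                          tissues = "islet", n_perm = 20, seed = 29),
    "zero-variance")
  expect_error(
    coexpression_msr_test("g1", expr, st, proximal_pool = paste0("g", 1:30),
                          n_perm = 10, seed = 1),
    "at least 2")
})
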