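test_that("empirical p follows the add-one formula and never reaches zero", {
  expect_equal(empirical_p(10, rep(0, 1000)), 1 / 1001)
  expect_equal(empirical_p(0, rep(5, 1000)), 1.0)
  nulls <- c(rep(100, 49), rep(0, 950))   # 49 of 999 >= obs
  expect_equal(empirical_p(10, nulls, "ge"), 50 / 1000)
  expect_equal(empirical_p(10, c(1, 2, 3), "le"), 1.0)
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("tissue-specific eQTL sets are the per-tissue set minus all others", {
  sig <- list(islet = c("a", "b", "c"), liver = c("b", "d"),
              muscle = character(0))
  sets <- tissue_specific_eqtls(sig)
  expect_equal(sets$specific$islet, c("a", "c"))
  expect_equal(sets$specific$liver, "d")
  expect_equal(sets$specific$muscle, character(0))
  # disjointness is invariant under tissue-order permutation
  perm <- tissue_specific_eqtls(sig[c("muscle", "liver", "islet")])
  all_specific <- unlist(perm$specific)
  expect_equal(anyDuplicated(all_specific), 0L)
  expect_setequal(unname(all_specific), unname(unlist(sets$specific)))
})

test_that("eQTL enrichment handles the degenerate extremes", {
  universe <- paste0("s", 1:30)
  spec <- list(islet = paste0("s", 1:5))
  sets <- tissue_specific_eqtls(spec)
  # query == specific set; nulls drawn from disjoint SNPs
  res <- eqtl_enrichment(list(islet = paste0("s", 1:5)), sets,
                         uniform_snp_sampler(paste0("x", 1:30)),
                         n_perm = 200, seed = 1)
  expect_true(is.na(res$fold))
  expect_equal(res$p_emp, 1 / 201)
  # disjoint query: observed 0, fold 0
  res0 <- eqtl_enrichment(list(islet = paste0("s", 21:25)), sets,
                          uniform_snp_sampler(universe),
                          n_perm = 200, seed = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$fold, 0)
})

test_that("small-universe eQTL enrichment p matches the subset-enumeration oracle", {
  universe <- paste0("s", 1:20)
  specific <- paste0("s", 1:4)
  query <- c("s1", "s2", "s7", "s8", "s9")   # observed overlap 2
  sets <- tissue_specific_eqtls(list(islet = specific))
  res <- eqtl_enrichment(list(islet = query), sets,
                         uniform_snp_sampler(universe),
                         n_perm = 4000, seed = 2)
  exact <- enumerate_subset_tail(universe, 5,
                                 function(s) sum(s %in% specific),
                                 observed = 2, tail = "ge")
  expect_equal(res$observed, 2)
  expect_equal(res$p_emp, exact, tolerance = 0.03)
  # identical seed reproduces the result exactly
  res2 <- eqtl_enrichment(list(islet = query), sets,
                          uniform_snp_sampler(universe),
                          n_perm = 4000, seed = 2)
  expect_identical(res, res2)
})

test_that("physiology-cluster enrichment is extreme for a self-query and exact on toy universes", {
  universe <- paste0("sig", 1:40)
  clusters <- list(secretion = paste0("sig", 1:5))
  res <- physiology_enrichment(paste0("sig", 1:5), clusters, universe,
                               n_perm = 400, seed = 3)
  expect_equal(res$p_emp, 1 / 401)
  expect_gt(res$fold, 5)

  # 3-signal query over a 6-signal universe: all C(6,3) = 20 subsets
  small_u <- paste0("u", 1:6)
  cl <- list(c1 = c("u1", "u2"))
  query <- c("u1", "u3", "u5")   # observed overlap 1
  res2 <- physiology_enrichment(query, cl, small_u, n_perm = 4000, seed = 4)
  exact <- enumerate_subset_tail(small_u, 3,
                                 function(s) sum(s %in% cl$c1),
                                 observed = 1, tail = "ge")
  expect_equal(res2$p_emp, exact, tolerance = 0.03)
  expect_error(physiology_enrichment("not_there", cl, small_u,
                                     n_perm = 10, seed = 1),
               "subset of the universe")
})

test_that("random physiology queries give fold near 1 on average", {
  universe <- paste0("sig", 1:60)
  clusters <- list(c1 = paste0("sig", 1:20))
  set.seed(5)
  folds <- vapply(1:30, function(i) {
    q <- sample(universe, 10)
    physiology_enrichment(q, clusters, universe, n_perm = 100,
                          seed = 100 + i)$fold
  }, numeric(1))
  # analytic mean overlap is hypergeometric: 10 * 20/60; fold centers on 1
  expect_equal(mean(folds), 1, tolerance = 0.15)
})

test_that("GWAS-catalog overlaps collapse index and proxies to one count per signal", {
  signal_snps <- list(
    sigA = c("rsA", "prxA1", "prxA2", "prxA3"),
    sigB = c("rsB", "prxB1"),
    sigC = c("rsC"))
  trait_sets <- list(trait1 = c("rsA", "prxA1", "prxA2", "prxA3"),
                     trait2 = c("nothing"))
  res <- gwascat_enrichment(signal_snps, trait_sets["trait1"],
                            query_signals = c("sigA", "sigB"),
                            n_perm = 100, seed = 6)
  expect_equal(res$observed, 1)   # all four sigA SNPs count once

  res0 <- gwascat_enrichment(signal_snps, trait_sets["trait2"],
                             query_signals = c("sigA", "sigB"),
                             n_perm = 100, seed = 6)
  expect_equal(res0$observed, 0)
  expect_equal(res0$fold, 0)

  expect_warning(
    gwascat_enrichment(signal_snps, list(empty = character(0)),
                       query_signals = "sigA", n_perm = 10, seed = 1),
    "empty SNP set")
})

test_that("tiny-universe GWAS-catalog p matches exhaustive enumeration", {
  signal_snps <- setNames(
    lapply(1:5, function(i) c(sprintf("rs%d", i), sprintf("prx%d", i))),
    paste0("sig", 1:5))
  trait <- list(t = c("rs1", "prx2"))
  query <- c("sig1", "sig3")   # observed 1
  res <- gwascat_enrichment(signal_snps, trait, query,
                            n_perm = 4000, seed = 7)
  exact <- enumerate_subset_tail(
    names(signal_snps), 2,
    function(s) sum(vapply(signal_snps[s],
                           function(x) any(x %in% trait$t), logical(1))),
    observed = 1, tail = "ge")
  expect_equal(res$p_emp, exact, tolerance = 0.03)
})

test_that("the BH utility thresholds nominal p values at the requested FDR", {
  ids <- paste0("e", 1:6)
  p <- c(0.001, 0.002, 0.003, 0.2, 0.5, 0.9)
  expect_equal(filter_eqtls_fdr(ids, p, fdr = 0.05), ids[1:3])
})

test_that("the stratified sampler draws matched SNPs from the same bin", {
  universe <- paste0("s", 1:20)
  bins <- setNames(rep(c("low", "high"), each = 10), universe)
  sampler <- stratified_snp_sampler(universe, bins)
  withr::with_seed(8, {
    for (i in 1:20) {
      drawn <- sampler(c("s1", "s15"))
      expect_equal(unname(bins[drawn]), c("low", "high"))
      expect_false(drawn[1] %in% c("s1"))
    }
  })
})
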