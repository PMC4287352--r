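test_that("the hypergeometric overlap matches exact enumeration", {
  # universe 10, query 4, reference 5, overlap 4:
  # P(X >= 4) = C(5,4) C(5,0) / C(10,4) = 5/210
  r <- overlap_test_counts(k = 4, n_query = 4, n_reference = 5,
                           universe_size = 10)
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)
  expect_equal(r$expected, 2)

  # no overlap between tiny sets in a huge universe is unremarkable
  expect_gt(overlap_test_counts(0, 5, 5, 10000)$p, 0.99)

  # id-based interface agrees with the count-based one
  q <- paste0("g", 1:4); ref <- paste0("g", c(1:4, 9))
  expect_equal(overlap_test(q, ref, 10)$p, 5 / 210, tolerance = 1e-12)

  expect_error(overlap_test_counts(0, 6, 6, 10), "universe")
  expect_error(overlap_test_counts(7, 6, 8, 100), "overlap")
})

test_that("hypergeometric upper tail equals one-sided Fisher's exact", {
  set.seed(21)
  for (i in 1:100) {
    N <- sample(50:500, 1)
    K <- sample(5:40, 1)
    n <- sample(5:40, 1)
    k <- sample(0:min(K, n), 1)
    p_hyper <- overlap_test_counts(k, n, K, N)$p
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    p_fisher <- fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p_hyper, p_fisher, tolerance = 1e-12)
  }
})

test_that("overlap p is non-increasing in k at fixed margins", {
  ps <- vapply(0:10, function(k) overlap_test_counts(k, 10, 20, 100)$p, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("trait signatures capture the planted drivers", {
  sim <- sim_adjusted(small_config(n_ctrl = 70, n_copd = 130))
  sig <- trait_signatures(sim$expr_adj, sim$phenotypes, p_max = 0.01,
                          n_perm = 3, seed = 22)
  drivers <- sim$truth$trait_drivers
  for (tr in names(drivers)) {
    expect_gte(mean(drivers[[tr]] %in% sig$signatures[[tr]]), 0.8)
  }
  # bit-reproducible
  sig2 <- trait_signatures(sim$expr_adj, sim$phenotypes, p_max = 0.01,
                           n_perm = 3, seed = 22)
  expect_identical(sig$signatures, sig2$signatures)
})

test_that("null and degenerate traits give calibrated or empty signatures", {
  nul <- sim_adjusted(null_config(n_ctrl = 60, n_copd = 60, n_genes = 300))
  ph <- nul$phenotypes
  sig <- trait_signatures(nul$expr_adj, ph, p_max = 0.01, n_perm = 2, seed = 23)
  # under the null each signature holds ~1% of genes
  sizes <- lengths(sig$signatures)
  expect_lt(mean(sizes), 0.03 * 300)

  # constant trait -> empty signature; scarce trait -> flagged
  ph$DLCO <- 1
  ph$BODE[-(1:5)] <- NA
  sig2 <- trait_signatures(nul$expr_adj, ph, p_max = 0.01, n_perm = 2, seed = 23)
  expect_length(sig2$signatures$DLCO, 0)
  expect_length(sig2$signatures$BODE, 0)
  expect_true("BODE" %in% sig2$flagged)
})

test_that("promoter-methylation trait screen singles out the driver hub", {
  sim <- sim_adjusted(small_config(n_ctrl = 70, n_copd = 130))
  regs <- sim$truth$regulators
  scr <- regulator_trait_screen(sim$meth_adj, regs, sim$ann, sim$phenotypes,
                                p_max = 0.05)
  expect_true(sim$truth$trait_driver %in% scr$all_traits)
  expect_identical(regulator_trait_screen(sim$meth_adj, regs, sim$ann,
                                          sim$phenotypes, p_max = 0)$all_traits,
                   character(0))
})

test_that("downstream-signature screen finds the driver and only the driver", {
  sim <- sim_adjusted(small_config(n_ctrl = 70, n_copd = 130))
  res <- run_causality(sim$meth_adj, sim$expr_adj, sim$ann, n_perm = 1,
                       seed = 24)
  s1 <- summarize_regulators(res$trios, "I")
  sig <- trait_signatures(sim$expr_adj, sim$phenotypes, p_max = 0.01,
                          n_perm = 1, seed = 24)
  universe <- rownames(sim$expr_adj$values)
  scr <- downstream_signature_screen(s1, sig$signatures, universe, p_max = 0.05)
  expect_identical(scr$all_traits, sim$truth$trait_driver)

  # shrinking p_max can only shrink the survivor list
  scr2 <- downstream_signature_screen(s1, sig$signatures, universe,
                                      p_max = 0.01)
  expect_true(all(scr2$all_traits %in% scr$all_traits))

  # empty signatures contribute p = 1 cells
  empty_sig <- setNames(rep(list(character(0)), 5), names(sig$signatures))
  scr3 <- downstream_signature_screen(s1, empty_sig, universe)
  expect_true(all(scr3$p == 1))
  expect_length(scr3$all_traits, 0)
})

test_that("collection enrichment skips oversized sets and ranks the match first", {
  universe <- sprintf("g%04d", 1:1000)
  query <- universe[1:20]
  collection <- list(exact = universe[1:20],
                     partial = universe[11:60],
                     unrelated = universe[501:540],
                     huge = sprintf("g%04d", 1:2000))
  res <- geneset_collection_enrichment(query, collection, universe,
                                       max_set_size = 1500)
  expect_false("huge" %in% res$set)   # 2000-gene set is never tested
  expect_identical(res$set[1], "exact")
  expect_lt(res$p[res$set == "exact"], res$p[res$set == "partial"])
  expect_error(geneset_collection_enrichment(character(0), collection,
                                             universe), "empty query")
})
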