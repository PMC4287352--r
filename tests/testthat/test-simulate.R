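test_that("simulated cohort has the configured shape and valid values", {
  sim <- simulate_methexpr(small_config())
  cfg <- sim$config
  n <- cfg$n_ctrl + cfg$n_copd
  expect_equal(dim(sim$meth), c(cfg$n_genes * cfg$probes_per_gene, n))
  expect_equal(dim(sim$expr), c(cfg$n_genes, n))
  expect_equal(sum(sim$meth$group == "CTRL"), cfg$n_ctrl)
  expect_equal(sum(sim$meth$group == "COPD"), cfg$n_copd)
  expect_true(all(sim$meth$values >= 0 & sim$meth$values <= 1))
  expect_true(all(is.finite(sim$expr$values)))
  # planted structure references generated features and partitions the trios
  expect_true(all(sim$truth$trios$probe_id %in% rownames(sim$meth$values)))
  expect_true(all(sim$truth$trios$trans_gene %in% rownames(sim$expr$values)))
  expect_true(all(sim$truth$trios$model %in% c("I", "II", "III")))
  # the default cohort mirrors the matched study arms
  def <- sim_config()
  expect_equal(def$n_ctrl, 52)
  expect_equal(def$n_copd, 100)
})

test_that("a noiseless chain is a perfect monotone relay", {
  cfg <- small_config(noise_sd = 0, probe_noise_sd = 0, trait_noise_sd = 0,
                      n_key_regulators = 1, downstream_counts = 10L,
                      frac_model2 = 0, n_confounded = 0,
                      covariate_effects = c(age = 0, sex = 0, packyears = 0),
                      n_ctrl = 15, n_copd = 15)
  sim <- simulate_methexpr(cfg)
  r <- sim$truth$key_regulators[1]
  probe <- paste0(r, "_p1")
  for (g in sim$truth$downstream[[r]]) {
    rho <- spearman_test(sim$meth$values[probe, ], sim$expr$values[g, ])$rho
    expect_equal(abs(rho), 1)
  }
})

test_that("a zero hypermethylation shift leaves island betas equal by group", {
  sim <- simulate_methexpr(small_config(hypermeth_shift = 0, n_ctrl = 300,
                                        n_copd = 300))
  isl <- sim$probes$probe_id[sim$probes$cpg_island]
  betas <- sim$meth$values[isl, , drop = FALSE]
  d <- rowMeans(betas[, sim$meth$group == "COPD"]) -
       rowMeans(betas[, sim$meth$group == "CTRL"])
  expect_lt(abs(mean(d)), 0.02)

  # and a positive shift hypermethylates islands in COPD
  sim2 <- simulate_methexpr(small_config(n_ctrl = 300, n_copd = 300))
  isl2 <- sim2$probes$probe_id[sim2$probes$cpg_island]
  d2 <- rowMeans(sim2$meth$values[isl2, sim2$meth$group == "COPD"]) -
        rowMeans(sim2$meth$values[isl2, sim2$meth$group == "CTRL"])
  expect_gt(mean(d2), 0.05)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(frac_model2 = 1.5), "frac_model2")
  expect_error(sim_config(probes_per_gene = 0), "probes_per_gene")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_genes = 50), "downstream_counts")
  expect_error(sim_config(n_key_regulators = 3,
                          downstream_counts = c(5L, 5L)),
               "downstream_counts")
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_methexpr(small_config(seed = 9))
  b <- simulate_methexpr(small_config(seed = 9))
  expect_identical(a$meth$values, b$meth$values)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth$trios, b$truth$trios)
  c <- simulate_methexpr(small_config(seed = 10))
  expect_false(identical(a$meth$values, c$meth$values))
})

test_that("planted cis links have detectable rank correlation at n = 200", {
  sim <- sim_adjusted(small_config(n_ctrl = 100, n_copd = 100))
  reg <- sim$truth$regulators
  pr <- sim$ann[!is.na(sim$ann$gene_id) & sim$ann$gene_id %in% reg, ]
  rhos <- vapply(seq_len(nrow(pr)), function(i)
    spearman_test(sim$meth_adj$values[pr$probe_id[i], ],
                  sim$expr_adj$values[pr$gene_id[i], ])$rho, 0)
  expect_gte(mean(abs(rhos) > 0.3), 0.9)
})

test_that("planted Model-I trios are conditionally independent given cis", {
  # at large n the mediation is clean: M indep T | C for planted chains
  sim <- sim_adjusted(small_config(n_ctrl = 1000, n_copd = 1000, n_genes = 40,
                                   n_key_regulators = 1,
                                   downstream_counts = 12L,
                                   frac_model2 = 0, n_confounded = 0))
  t1 <- sim$truth$trios[sim$truth$trios$model == "I", ]
  ps <- vapply(seq_len(nrow(t1)), function(i)
    conditional_independence(sim$meth_adj$values[t1$probe_id[i], ],
                             sim$expr_adj$values[t1$cis_gene[i], ],
                             sim$expr_adj$values[t1$trans_gene[i], ], "I"), 0)
  expect_gt(median(ps), 0.2)
})

test_that("shuffle_samples permutes exactly the requested labels", {
  sim <- simulate_methexpr(small_config(n_ctrl = 10, n_copd = 10))
  s0 <- shuffle_samples(sim$expr, 0, seed = 3)
  expect_identical(s0$pairing$true_sample, s0$pairing$expr_label)

  s2 <- shuffle_samples(sim$expr, 2, seed = 3)
  expect_equal(sum(s2$pairing$true_sample != s2$pairing$expr_label), 2L)

  s10a <- shuffle_samples(sim$expr, 10, seed = 5)
  s10b <- shuffle_samples(sim$expr, 10, seed = 5)
  expect_identical(s10a$expr$values, s10b$expr$values)
  expect_equal(sum(s10a$pairing$true_sample != s10a$pairing$expr_label), 10L)

  expect_error(shuffle_samples(sim$expr, 21), "n_swaps")
})
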