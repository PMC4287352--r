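make_genes <- function(...) {
  g <- list(...)
  data.frame(gene_id = vapply(g, `[[`, "", 1),
             chromosome = vapply(g, `[[`, "", 2),
             tss = as.integer(vapply(g, `[[`, "", 3)),
             strand = vapply(g, `[[`, "", 4), stringsAsFactors = FALSE)
}

make_probes <- function(ids, chrom, pos) {
  data.frame(probe_id = ids, chromosome = chrom, position = as.integer(pos),
             cpg_island = TRUE, gene_id = NA_character_,
             tss_distance = NA_integer_, stringsAsFactors = FALSE)
}

test_that("probe mapping respects the strict 10 kb radius and signs distances", {
  genes <- make_genes(c("gA", "chr1", "100000", "+"),
                      c("gB", "chr1", "300000", "-"))
  probes <- make_probes(c("p_in", "p_edge", "p_out", "p_neg"),
                        "chr1", c(109999, 110000, 150000, 295000))
  m <- map_probes(probes, genes)
  expect_identical(m$gene_id, c("gA", NA, NA, "gB"))
  expect_equal(m$tss_distance[1], 9999L)      # downstream of + strand TSS
  expect_equal(m$tss_distance[4], 5000L)      # upstream in genome, downstream for -
  # a probe on an unannotated chromosome stays unassigned
  solo <- map_probes(make_probes("px", "chrX", 1000), genes)
  expect_true(is.na(solo$gene_id))
})

test_that("equidistant probes break ties to the smaller gene id, flagged", {
  genes <- make_genes(c("gZ", "chr1", "1000", "+"),
                      c("gA", "chr1", "3000", "+"))
  m <- map_probes(make_probes("p", "chr1", 2000), genes)
  expect_identical(m$gene_id, "gA")
  expect_true(m$tie)
})

test_that("covariate adjustment preserves means exactly and is idempotent", {
  set.seed(4)
  n <- 40
  cov <- data.frame(sample_id = sprintf("s%02d", 1:n),
                    age = rnorm(n, 60, 10),
                    sex = sample(c("F", "M"), n, TRUE))
  v <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("f", 1:5), cov$sample_id))
  v[5, ] <- 2 * cov$age + 5                     # perfectly explained feature
  om <- omics_matrix(v, "expression")
  adj <- adjust_covariates(om, cov)
  expect_equal(rowMeans(adj$values), rowMeans(v), tolerance = 1e-10)
  expect_equal(unname(adj$values[5, ]), rep(mean(v[5, ]), n), tolerance = 1e-8)
  twice <- adjust_covariates(adj, cov)
  expect_equal(twice$values, adj$values, tolerance = 1e-10)

  # a collinear design column is dropped with a warning
  cov$age2 <- cov$age * 2
  expect_warning(adjust_covariates(om, cov), "rank-deficient")
})

test_that("a null covariate leaves features nearly untouched", {
  set.seed(5)
  n <- 200
  cov <- data.frame(sample_id = sprintf("s%03d", 1:n), junk = rnorm(n))
  v <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(paste0("f", 1:3), cov$sample_id))
  adj <- adjust_covariates(omics_matrix(v, "expression"), cov)
  expect_lt(max(abs(adj$values - v)) / sd(v), 0.5)
  expect_gt(cor(as.vector(adj$values), as.vector(v)), 0.99)
})

test_that("probe filters apply island, window and multiplicity rules", {
  ann <- data.frame(probe_id = paste0("p", 1:6), chromosome = "chr1",
                    position = 1:6, cpg_island = c(T, T, F, F, T, T),
                    gene_id = c("g1", "g1", "g2", NA, "g3", "g2"),
                    tss_distance = c(100L, -2000L, 500L, 3L, 900L, 50L),
                    stringsAsFactors = FALSE)
  expect_identical(filter_probes(ann)$probe_id, paste0("p", c(1, 2, 3, 5, 6)))
  expect_true(all(filter_probes(ann, require_island = TRUE)$cpg_island))
  expect_true(all(abs(filter_probes(ann, tss_window = 1000)$tss_distance) < 1000))
  two <- filter_probes(ann, min_probes_per_gene = 2)
  expect_setequal(unique(two$gene_id), c("g1", "g2"))
})

test_that("the differential t-test finds separated groups and is symmetric", {
  set.seed(6)
  g <- rep(c("CTRL", "COPD"), each = 50)
  v <- rbind(sep = c(rnorm(50, 0), rnorm(50, 3)),
             null = rnorm(100),
             const = rep(1, 100))
  colnames(v) <- sprintf("s%03d", 1:100)
  om <- omics_matrix(v, "expression", group = g)
  d <- differential(om)
  expect_lt(d$p[d$feature_id == "sep"], 1e-10)
  expect_identical(d$direction[d$feature_id == "sep"], "up")
  expect_gt(d$p[d$feature_id == "null"], 0.01)
  expect_equal(d$p[d$feature_id == "const"], 1)
  expect_true(is.na(d$direction[d$feature_id == "const"]))

  # swapping labels keeps p, flips direction
  d2 <- differential(om, groups = ifelse(g == "CTRL", "COPD", "CTRL"))
  expect_equal(d2$p, d$p)
  expect_identical(d2$direction[d$feature_id == "sep"], "down")

  # pooled t matches stats::t.test with var.equal = TRUE
  ref <- t.test(v["sep", g == "COPD"], v["sep", g == "CTRL"], var.equal = TRUE)
  expect_equal(d$t[d$feature_id == "sep"], unname(ref$statistic))
  # Welch variant matches stats::t.test default
  dw <- differential(om, var_equal = FALSE)
  refw <- t.test(v["sep", g == "COPD"], v["sep", g == "CTRL"])
  expect_equal(dw$t[dw$feature_id == "sep"], unname(refw$statistic))
})

test_that("the permutation FDR follows the mean-permuted / observed formula", {
  expect_equal(signif(fdr_report(0.01, 362095, 518)$fdr, 2), 0.0014)
  expect_equal(signif(fdr_report(0.01, 19173, 2)$fdr, 2), 1.0e-4)
  expect_equal(fdr_report(0.01, 100, c(0L, 0L, 0L))$fdr, 0)
  expect_true(is.na(fdr_report(0.01, 0, c(5L, 5L))$fdr))
  expect_equal(fdr_report(0.01, 10, c(50L, 70L))$fdr, 1)  # clipped
})

test_that("differential FDR is near 1 under the null and small under signal", {
  set.seed(7)
  g <- rep(c("CTRL", "COPD"), each = 30)
  null_v <- matrix(rnorm(300 * 60), 300, 60,
                   dimnames = list(paste0("f", 1:300), sprintf("s%02d", 1:60)))
  fd <- permutation_fdr_differential(omics_matrix(null_v, "expression", group = g),
                                     p_threshold = 0.05, n_perm = 50, seed = 2)
  expect_gte(fd$fdr, 0.5)

  sig_v <- null_v + outer(rep(c(2, 0), c(100, 200)), as.numeric(g == "COPD"))
  fs <- permutation_fdr_differential(omics_matrix(sig_v, "expression", group = g),
                                     p_threshold = 0.01, n_perm = 50, seed = 2)
  expect_lt(fs$fdr, 0.1)

  # reproducible given the seed
  fs2 <- permutation_fdr_differential(omics_matrix(sig_v, "expression", group = g),
                                      p_threshold = 0.01, n_perm = 50, seed = 2)
  expect_identical(fs$permuted, fs2$permuted)

  # monotonicity: tightening the threshold never increases counts
  loose <- permutation_fdr_differential(omics_matrix(sig_v, "expression", group = g),
                                        p_threshold = 0.05, n_perm = 20, seed = 3)
  tight <- permutation_fdr_differential(omics_matrix(sig_v, "expression", group = g),
                                        p_threshold = 0.005, n_perm = 20, seed = 3)
  expect_lte(tight$observed, loose$observed)
  expect_true(all(tight$permuted <= loose$permuted))
})
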