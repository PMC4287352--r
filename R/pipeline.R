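#' Pipeline configuration
#'
#' Collects every stage threshold and permutation count of the end-to-end
#' analysis.  Defaults reproduce the pipeline's standard operating point:
#' cis anchoring at Spearman p < 0.01, trans scan at p < 1e-5, causality
#' chain association at p < 1e-4 with conditional independence at p > 0.01,
#' key regulators at mean + 2 SD, trait signatures at p < 0.01 and overlap
#' screens at p < 0.05.
#'
#' @param p_cis cis association threshold.
#' @param p_trans trans scan threshold (candidate generation).
#' @param p_assoc chain association threshold inside the causality test.
#' @param p_indep conditional-independence threshold (verdicts require the
#'   p-value to exceed it).
#' @param key_sd key-regulator rule: mean + `key_sd` standard deviations.
#' @param p_trait_signature trait-signature threshold.
#' @param p_trait_screen threshold for the regulator/trait screens.
#' @param n_perm_differential label permutations for differential FDRs.
#' @param n_perm_assoc expression permutations for association/causality and
#'   signature FDRs.
#' @param max_probe_dist probe-to-TSS assignment radius (bp).
#' @param seed integer seed fanned out to per-stage substreams.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(p_cis = 0.01, p_trans = 1e-5, p_assoc = 1e-4,
                            p_indep = 0.01, key_sd = 2,
                            p_trait_signature = 0.01, p_trait_screen = 0.05,
                            n_perm_differential = 100, n_perm_assoc = 5,
                            max_probe_dist = 10000, seed = 1) {
  cfg <- list(p_cis = p_cis, p_trans = p_trans, p_assoc = p_assoc,
              p_indep = p_indep, key_sd = key_sd,
              p_trait_signature = p_trait_signature,
              p_trait_screen = p_trait_screen,
              n_perm_differential = n_perm_differential,
              n_perm_assoc = n_perm_assoc, max_probe_dist = max_probe_dist,
              seed = as.integer(seed))
  for (f in c("p_cis", "p_trans", "p_assoc", "p_trait_signature",
              "p_trait_screen")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("invalid '%s': must be in [0, 1]", f))
  }
  for (f in c("n_perm_differential", "n_perm_assoc"))
    if (cfg[[f]] < 1) stop(sprintf("invalid '%s': must be >= 1", f))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file to read or write.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis end-to-end
#'
#' Stages, in order: sample matching, probe-to-gene mapping, covariate
#' adjustment, differential methylation/expression with permutation FDR,
#' cis/trans association scans, trio causality test with per-model FDRs,
#' regulator summarisation and key-regulator detection (2 SD and 3 SD
#' rules, plus the reversed Model-II hub analysis), scale-free fit, trait
#' signatures, and both regulator/trait screens.  A funnel of stage counts
#' is reported via `message()` when `verbose = TRUE`.
#'
#' @param data a list with `meth`, `expr`, `probes`, `genes`, `covariates`,
#'   `phenotypes` — e.g. the output of [simulate_methexpr()].
#' @param config a [pipeline_config()].
#' @param match run the sample-matching stage (set `FALSE` when the columns
#'   are already aligned).
#' @param verbose print the stage-count funnel.
#' @return A list bundle with elements `match_report`, `annotation`,
#'   `differential` (per modality, each with an [fdr_report()]), `cis_pairs`,
#'   `causality` (trios + FDRs), `regulators` (summaries, key sets,
#'   scale-free fits for both models), `traits` (signatures + screens),
#'   `funnel` (named counts) and `config`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), match = TRUE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  funnel <- list()

  ## --- sample matching -------------------------------------------------
  ann <- map_probes(data$probes, data$genes, config$max_probe_dist)
  if (match) {
    rep <- match_samples(data$meth, data$expr, ann, p_cis = config$p_cis)
    aligned <- apply_matching(data$meth, data$expr, rep)
    say("matching: %d pairs matched in %d iteration(s), %d dropped",
        length(rep$mapping), rep$iterations, nrow(rep$dropped))
  } else {
    rep <- NULL
    aligned <- list(meth = data$meth, expr = data$expr)
  }
  meth <- aligned$meth
  expr <- aligned$expr
  funnel$matched_samples <- ncol(meth$values)

  ## --- preprocessing ---------------------------------------------------
  funnel$mapped_probes <- sum(!is.na(ann$gene_id))
  say("mapping: %d/%d probes assigned to a gene within %d bp",
      funnel$mapped_probes, nrow(ann), config$max_probe_dist)
  cov <- data$covariates[data$covariates$sample_id %in% sample_ids(meth), ,
                         drop = FALSE]
  meth_adj <- adjust_covariates(meth, cov)
  expr_adj <- adjust_covariates(expr, cov)

  seed <- config$seed
  diff_meth <- differential(meth_adj)
  diff_expr <- differential(expr_adj)
  fdr_dm <- permutation_fdr_differential(meth_adj, p_threshold = config$p_cis,
                                         n_perm = config$n_perm_differential,
                                         seed = seed + 11L)
  fdr_de <- permutation_fdr_differential(expr_adj, p_threshold = config$p_cis,
                                         n_perm = config$n_perm_differential,
                                         seed = seed + 12L)
  funnel$diff_meth <- fdr_dm$observed
  funnel$diff_expr <- fdr_de$observed
  say("differential: %d methylation / %d expression features at p < %g (FDR %.3g / %.3g)",
      fdr_dm$observed, fdr_de$observed, config$p_cis,
      fdr_dm$fdr, fdr_de$fdr)

  ## --- association + causality ----------------------------------------
  cis <- find_cis_pairs(meth_adj, expr_adj, ann, config$p_cis)
  funnel$cis_pairs <- nrow(cis)
  say("association: %d cis pairs at p < %g", nrow(cis), config$p_cis)
  caus <- run_causality(meth_adj, expr_adj, ann,
                        p_cis_anchor = config$p_cis, p_trans = config$p_trans,
                        thresholds = causality_thresholds(config$p_cis,
                                                          config$p_assoc,
                                                          config$p_indep),
                        n_perm = config$n_perm_assoc, seed = seed + 21L)
  funnel$candidate_trios <- caus$candidates
  funnel$model1_trios <- sum(caus$trios$model == "I")
  funnel$model2_trios <- sum(caus$trios$model == "II")
  say("causality: %d candidates -> %d Model I (FDR %s), %d Model II (FDR %s)",
      caus$candidates, funnel$model1_trios,
      format(signif(caus$fdr$I$fdr, 2)), funnel$model2_trios,
      format(signif(caus$fdr$II$fdr, 2)))

  ## --- regulators ------------------------------------------------------
  sum1 <- summarize_regulators(caus$trios, "I")
  sum2 <- summarize_regulators(caus$trios, "II")
  keys2sd <- key_regulators(sum1, config$key_sd)
  keys3sd <- key_regulators(sum1, 3)
  sf1 <- scale_free_fit(sum1)
  funnel$regulating_genes <- length(sum1)
  funnel$key_regulators <- length(keys2sd)
  say("regulators: %d regulating genes, %d key regulators at mean + %g SD",
      length(sum1), length(keys2sd), config$key_sd)

  ## --- phenotype screens -----------------------------------------------
  traits <- NULL
  if (!is.null(data$phenotypes)) {
    sig <- trait_signatures(expr_adj, data$phenotypes,
                            p_max = config$p_trait_signature,
                            n_perm = config$n_perm_assoc, seed = seed + 31L)
    meth_screen <- regulator_trait_screen(meth_adj, keys2sd, ann,
                                          data$phenotypes,
                                          p_max = config$p_trait_screen)
    dn_screen <- downstream_signature_screen(sum1[names(sum1) %in% keys2sd],
                                             sig$signatures,
                                             universe = feature_ids(expr_adj),
                                             p_max = config$p_trait_screen)
    traits <- list(signatures = sig, methylation_screen = meth_screen,
                   downstream_screen = dn_screen)
    funnel$all_trait_regulators <- length(dn_screen$all_traits)
    say("screens: %d key regulator(s) overlap all trait signatures [%s]",
        length(dn_screen$all_traits),
        paste(dn_screen$all_traits, collapse = ", "))
  }

  list(match_report = rep, annotation = ann,
       matrices = list(meth = meth_adj, expr = expr_adj),
       differential = list(methylation = list(table = diff_meth, fdr = fdr_dm),
                           expression = list(table = diff_expr, fdr = fdr_de)),
       cis_pairs = cis, causality = caus,
       regulators = list(model1 = sum1, model2 = sum2,
                         key_2sd = keys2sd, key_3sd = keys3sd,
                         scale_free = sf1),
       traits = traits, funnel = funnel, config = config)
}
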