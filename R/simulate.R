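#' Configuration for the synthetic methylation/expression simulator
#'
#' Defines the study conditions for [simulate_methexpr()]: a two-group
#' (CTRL/COPD) cohort with promoter methylation probes, cis
#' methylation-to-expression links of both signs, a scale-free set of
#' regulators (a few hubs with many downstream targets, many regulators with
#' few), a minority of reversed (expression-to-methylation, "Model II")
#' chains, a handful of confounded methylation/expression pairs, additive
#' covariate effects, and five disease-severity traits driven by one hub's
#' downstream genes.
#'
#' @param n_ctrl,n_copd samples per group (defaults 52 and 100).
#' @param n_genes number of genes on the synthetic chromosome.
#' @param probes_per_gene promoter methylation probes per gene (>= 1).
#' @param n_key_regulators number of planted hub regulators; the first
#'   `n_key_regulators` entries of `downstream_counts` are the hubs.
#' @param downstream_counts integer vector of downstream-target counts, one
#'   per regulator (hubs first).  The default plants hubs with 40--80 targets
#'   plus 35 minor regulators with 1--5 targets, giving the heavy-tailed
#'   degree distribution the key-regulator test assumes.
#' @param frac_model2 fraction (of the total number of Model-I chains) of
#'   reversed chains in which a source gene's expression drives another
#'   gene's promoter methylation.
#' @param n_confounded number of confounded pairs where a latent factor
#'   drives both a gene's methylation and another gene's expression with no
#'   cis mediation.
#' @param cis_effect_sd magnitude of the cis methylation-to-expression
#'   coefficient (logit-beta scale).
#' @param trans_effect_sd magnitude of the trans (regulator expression to
#'   downstream expression, or source expression to target methylation)
#'   coefficient.
#' @param noise_sd residual standard deviation of gene expression and of the
#'   trans-driven part of target-gene methylation (logit scale).
#' @param probe_noise_sd measurement noise of individual probes around the
#'   gene-level promoter methylation latent (logit scale).  Array beta
#'   estimates are smoothed over neighbouring probes, so measurement noise
#'   is small relative to the unit-variance biological signal.
#' @param frac_positive_cis probability that a cis coefficient is positive;
#'   the default 0.45 reflects that promoter methylation silences slightly
#'   more often than it activates.
#' @param hypermeth_shift logit-scale methylation increase of CpG-island
#'   promoters in the COPD group.
#' @param island_frac fraction of promoters flagged as CpG islands.
#' @param covariate_effects named numeric vector (age, sex, packyears): the
#'   standard deviation of per-gene coefficients on the standardised
#'   covariates.
#' @param trait_noise_sd residual standard deviation of the severity traits.
#' @param trait_missing fraction of trait values set missing, emulating
#'   incomplete clinical measurement.
#' @param seed integer seed; all outputs are reproducible from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_ctrl = 52, n_copd = 100, n_genes = 500,
                       probes_per_gene = 2, n_key_regulators = 5,
                       downstream_counts = NULL, frac_model2 = 0.05,
                       n_confounded = 10, cis_effect_sd = 1,
                       trans_effect_sd = 1, noise_sd = 0.6,
                       probe_noise_sd = 0.25,
                       frac_positive_cis = 0.45, hypermeth_shift = 0.5,
                       island_frac = 0.6,
                       covariate_effects = c(age = 0.3, sex = 0.3, packyears = 0.3),
                       trait_noise_sd = 0.5, trait_missing = 0.15, seed = 1) {
  if (is.null(downstream_counts)) {
    hubs <- if (n_key_regulators > 0) round(seq(80, 40, length.out = n_key_regulators)) else integer(0)
    minors <- rep(c(5L, 4L, 3L, 2L, 1L), times = c(2L, 3L, 5L, 10L, 15L))
    downstream_counts <- c(hubs, minors)
  }
  cfg <- list(n_ctrl = n_ctrl, n_copd = n_copd, n_genes = n_genes,
              probes_per_gene = probes_per_gene,
              n_key_regulators = n_key_regulators,
              downstream_counts = as.integer(downstream_counts),
              frac_model2 = frac_model2, n_confounded = n_confounded,
              cis_effect_sd = cis_effect_sd, trans_effect_sd = trans_effect_sd,
              noise_sd = noise_sd, probe_noise_sd = probe_noise_sd,
              frac_positive_cis = frac_positive_cis,
              hypermeth_shift = hypermeth_shift, island_frac = island_frac,
              covariate_effects = covariate_effects,
              trait_noise_sd = trait_noise_sd, trait_missing = trait_missing,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 0) {
    v <- cfg[[field]]
    if (length(v) < 1L || any(!is.finite(v)) || any(v < min) || any(v != round(v)))
      stop(sprintf("invalid '%s': must be integer count(s) >= %d", field, min))
  }
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop(sprintf("invalid '%s': must be a fraction in [0, 1]", field))
  }
  for (f in c("n_ctrl", "n_copd", "n_genes", "n_key_regulators", "n_confounded"))
    chk_count(f)
  chk_count("probes_per_gene", min = 1)
  for (f in c("frac_model2", "frac_positive_cis", "island_frac",
              "trait_missing"))
    chk_frac(f)
  for (f in c("cis_effect_sd", "trans_effect_sd", "noise_sd",
              "probe_noise_sd", "hypermeth_shift", "trait_noise_sd"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("invalid '%s': must be a non-negative real", f))
  dc <- cfg$downstream_counts
  if (length(dc) < cfg$n_key_regulators)
    stop("invalid 'downstream_counts': need at least one entry per key regulator")
  if (any(dc < 0)) stop("invalid 'downstream_counts': negative count")
  n_reg <- length(dc)
  n_m2 <- round(cfg$frac_model2 * sum(dc))
  n_src <- if (n_m2 > 0) max(1L, ceiling(n_m2 / 25)) else 0L
  used <- n_reg + sum(dc) + n_m2 + n_src + 2L * cfg$n_confounded
  if (used > cfg$n_genes)
    stop(sprintf(paste0("invalid 'downstream_counts': planted structure needs ",
                        "%d genes but n_genes = %d"), used, cfg$n_genes))
  invisible(cfg)
}

inv_logit <- function(x) stats::plogis(x)

#' Simulate a paired methylation/expression cohort with planted causality
#'
#' Generates every input the pipeline consumes, together with the ground
#' truth of the planted structure.  Methylation is generated on the logit
#' scale and mapped to beta values in \[0, 1\]; each gene has a latent
#' promoter methylation level shared by its probes, shifted upwards in the
#' COPD group for CpG-island promoters.  Every non-downstream gene's
#' expression carries a cis term on its promoter methylation (sign positive
#' with probability `frac_positive_cis`).  Planted chains:
#'
#' * Model I: regulator methylation -> regulator (cis) expression ->
#'   downstream gene expression (downstream genes carry no cis term of their
#'   own, so the chain is fully mediated).
#' * Model II: source gene expression -> target gene methylation -> target
#'   (cis) expression.
#' * Confounded ("Model III"): a latent factor drives both a gene's
#'   methylation and a partner gene's expression; no cis mediation.
#'
#' Five severity traits (DLCO, BODE, FEV1pp, FEV1/FVC, emphysema) are driven
#' by the first hub's downstream expression: DLCO, FEV1pp and FEV1/FVC
#' decrease with the severity latent while BODE and emphysema increase.
#'
#' @param config a [sim_config()].
#' @return A list with elements `meth` and `expr` ([omics_matrix()]s),
#'   `probes` and `genes` (annotation data frames), `covariates`,
#'   `phenotypes`, `truth` (planted trios, key regulators, downstream sets,
#'   trait drivers, identity sample pairing) and `config`.
#' @seealso [shuffle_samples()] to create mislabeled fixtures for the
#'   sample-matching stage.
#' @export
simulate_methexpr <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_ctrl + config$n_copd
  samples <- sprintf("S%03d", seq_len(n))
  group <- setNames(rep(c("CTRL", "COPD"), c(config$n_ctrl, config$n_copd)),
                    samples)
  is_copd <- as.numeric(group == "COPD")

  ## gene layout: one synthetic chromosome, genes every 100 kb
  ng <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(ng))
  genes <- data.frame(gene_id = gene_ids, chromosome = "chrS",
                      tss = 100000L * seq_len(ng),
                      strand = sample(c("+", "-"), ng, replace = TRUE),
                      stringsAsFactors = FALSE)
  island <- setNames(rbinom(ng, 1L, config$island_frac) == 1L, gene_ids)

  ## role assignment
  dc <- config$downstream_counts
  n_reg <- length(dc)
  n_m2 <- round(config$frac_model2 * sum(dc))
  n_src <- if (n_m2 > 0) max(1L, ceiling(n_m2 / 25)) else 0L
  pool <- sample(gene_ids)
  take <- function(k) {
    if (k == 0L) return(character(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  regulators <- take(n_reg)
  hubs <- regulators[seq_len(config$n_key_regulators)]
  downstream <- vector("list", n_reg)
  names(downstream) <- regulators
  for (i in seq_len(n_reg)) downstream[[i]] <- take(dc[i])
  m2_sources <- if (n_src > 0) take(n_src) else character(0)
  m2_targets <- if (n_m2 > 0) take(n_m2) else character(0)
  ## round-robin assignment of targets to sources
  m2_source_of <- if (n_m2 > 0)
    setNames(rep(m2_sources, length.out = n_m2), m2_targets) else character(0)
  conf_m <- if (config$n_confounded > 0) take(config$n_confounded) else character(0)
  conf_t <- if (config$n_confounded > 0) take(config$n_confounded) else character(0)
  all_downstream <- unlist(downstream, use.names = FALSE)

  ## covariates
  covariates <- data.frame(
    sample_id = samples,
    age = round(rnorm(n, 65, 8)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    packyears = pmax(0, round(rnorm(n, 35, 20))),
    stringsAsFactors = FALSE)
  zcov <- cbind(age = as.numeric(scale(covariates$age)),
                sex = as.numeric(scale(as.numeric(covariates$sex == "M"))),
                packyears = as.numeric(scale(covariates$packyears)))
  ce <- config$covariate_effects
  cov_coef <- matrix(rnorm(ng * 3L, 0, rep(ce, each = ng)), ng, 3L,
                     dimnames = list(gene_ids, colnames(zcov)))
  cov_term <- cov_coef %*% t(zcov)   # genes x samples

  ## gene-level promoter methylation latent (logit scale)
  mu <- rnorm(ng, 0, 0.5)
  shift_term <- outer(as.numeric(island) * config$hypermeth_shift, is_copd)
  m_latent <- mu + shift_term + matrix(rnorm(ng * n), ng, n)
  rownames(m_latent) <- gene_ids
  colnames(m_latent) <- samples

  ## cis coefficients: downstream genes and confounded partners are fully
  ## driven in trans and carry no cis term of their own
  cis_sign <- ifelse(runif(ng) < config$frac_positive_cis, 1, -1)
  b <- setNames(cis_sign * config$cis_effect_sd, gene_ids)
  b[c(all_downstream, conf_t)] <- 0
  a <- setNames(rnorm(ng, 0, 0.5), gene_ids)

  expr <- matrix(NA_real_, ng, n, dimnames = list(gene_ids, samples))
  base_expr <- function(g) {
    a[g] + b[g] * m_latent[g, ] + cov_term[g, ] +
      rnorm(n, 0, config$noise_sd)
  }

  ## Model-II sources first: their expression drives target methylation
  for (g in m2_sources) expr[g, ] <- base_expr(g)
  if (n_m2 > 0) {
    g2_sign <- setNames(sample(c(-1, 1), n_m2, replace = TRUE), m2_targets)
    for (g in m2_targets) {
      src <- m2_source_of[[g]]
      zsrc <- as.numeric(scale(expr[src, ]))
      m_latent[g, ] <- mu[match(g, gene_ids)] +
        shift_term[match(g, gene_ids), ] +
        g2_sign[[g]] * config$trans_effect_sd * zsrc +
        rnorm(n, 0, config$noise_sd)
    }
  }

  ## remaining genes with a cis term (regulators, Model-II targets, background)
  rest <- setdiff(gene_ids, c(m2_sources, all_downstream, conf_t))
  for (g in rest) expr[g, ] <- base_expr(g)

  ## Model-I downstream genes: trans-driven by their regulator's expression
  trans_sign <- setNames(sample(c(-1, 1), length(all_downstream), replace = TRUE),
                         all_downstream)
  for (i in seq_len(n_reg)) {
    r <- regulators[i]
    for (g in downstream[[i]]) {
      expr[g, ] <- a[g] + trans_sign[[g]] * config$trans_effect_sd * expr[r, ] +
        cov_term[g, ] + rnorm(n, 0, config$noise_sd)
    }
  }

  ## confounded partners: a direct methylation -> trans-expression path
  ## that bypasses the cis gene (no mediation by its expression)
  if (length(conf_t) > 0) {
    conf_sign <- sample(c(-1, 1), length(conf_t), replace = TRUE)
    for (i in seq_along(conf_t)) {
      g <- conf_t[i]
      expr[g, ] <- a[g] + conf_sign[i] * config$trans_effect_sd *
        m_latent[conf_m[i], ] + cov_term[g, ] + rnorm(n, 0, config$noise_sd)
    }
  }

  ## probes: beta values around the gene latent, within +/- 5 kb of the TSS
  ppg <- config$probes_per_gene
  np <- ng * ppg
  probe_gene <- rep(gene_ids, each = ppg)
  probe_ids <- sprintf("%s_p%d", probe_gene, rep(seq_len(ppg), times = ng))
  offsets <- sample(setdiff(-5000:5000, 0L), np, replace = TRUE)
  probe_offset <- rnorm(np, 0, 0.3)
  beta <- inv_logit(m_latent[probe_gene, , drop = FALSE] + probe_offset +
                    matrix(rnorm(np * n, 0, config$probe_noise_sd), np, n))
  rownames(beta) <- probe_ids
  probes <- data.frame(probe_id = probe_ids, chromosome = "chrS",
                       position = genes$tss[match(probe_gene, gene_ids)] + offsets,
                       cpg_island = island[probe_gene],
                       gene_id = NA_character_, tss_distance = NA_integer_,
                       stringsAsFactors = FALSE, row.names = NULL)

  ## severity traits from the first hub's downstream expression.  Each trait
  ## is a differently weighted sum of the driver's downstream program (five
  ## clinical measures reflect different facets of severity), and each trait
  ## is measured in a different fraction of patients, so the five trait
  ## signatures are related but not redundant.
  driver <- if (length(hubs) > 0 && length(downstream[[hubs[1]]]) > 0) hubs[1] else NA_character_
  trait_names <- c("DLCO", "BODE", "FEV1pp", "FEV1.FVC", "emphysema")
  trait_sign <- setNames(c(-1, 1, -1, -1, 1), trait_names)
  # relative missingness pattern of the five measures (BODE near-complete,
  # emphysema scored in far fewer patients); scaled by trait_missing
  trait_miss_rel <- setNames(c(1, 0.15, 1.25, 1.25, 2.5), trait_names)
  phenotypes <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  if (!is.na(driver)) {
    dg <- downstream[[driver]]
    zt <- sweep(scale(t(expr[dg, , drop = FALSE])), 2L, trans_sign[dg], "*")
  }
  trait_weights <- list()
  trait_drivers <- list()
  for (tr in trait_names) {
    if (!is.na(driver)) {
      w <- runif(length(dg))
      names(w) <- dg
      sev_t <- as.numeric(scale(zt %*% w))
      trait_weights[[tr]] <- w
      trait_drivers[[tr]] <- dg[w >= 0.5]
    } else {
      sev_t <- rnorm(n)
    }
    v <- trait_sign[[tr]] * sev_t + rnorm(n, 0, config$trait_noise_sd)
    miss <- min(1, config$trait_missing * trait_miss_rel[[tr]])
    v[runif(n) < miss] <- NA_real_
    phenotypes[[tr]] <- v
  }

  ## ground truth
  trios <- data.frame(probe_id = character(0), cis_gene = character(0),
                      trans_gene = character(0), model = character(0),
                      stringsAsFactors = FALSE)
  add_trios <- function(gene, partners, model) {
    pr <- probe_ids[probe_gene == gene]
    if (length(partners) == 0) return(NULL)
    data.frame(probe_id = rep(pr, each = length(partners)),
               cis_gene = gene, trans_gene = rep(partners, times = length(pr)),
               model = model, stringsAsFactors = FALSE)
  }
  t1 <- do.call(rbind, lapply(regulators, function(r)
    add_trios(r, downstream[[r]], "I")))
  t2 <- if (n_m2 > 0) do.call(rbind, lapply(m2_targets, function(g)
    add_trios(g, m2_source_of[[g]], "II"))) else NULL
  t3 <- if (length(conf_m) > 0) do.call(rbind, lapply(seq_along(conf_m),
    function(i) add_trios(conf_m[i], conf_t[i], "III"))) else NULL
  trios <- rbind(trios, t1, t2, t3)

  truth <- list(
    trios = trios,
    key_regulators = hubs,
    regulators = regulators,
    downstream = downstream,
    model2_sources = m2_sources,
    model2_targets = m2_targets,
    confounded = if (length(conf_m) > 0)
      data.frame(meth_gene = conf_m, expr_gene = conf_t,
                 stringsAsFactors = FALSE) else NULL,
    trait_driver = driver,
    trait_drivers = if (!is.na(driver)) trait_drivers else NULL,
    trait_weights = if (!is.na(driver)) trait_weights else NULL,
    pairing = setNames(samples, samples))

  list(meth = omics_matrix(beta, "methylation-beta", group = group),
       expr = omics_matrix(expr, "expression", group = group),
       probes = probes, genes = genes, covariates = covariates,
       phenotypes = phenotypes, truth = truth, config = config)
}

#' Permute sample labels of an expression matrix
#'
#' Fixture generator for the sample-matching stage: relabels `n_swaps`
#' randomly chosen sample columns by a cyclic shift (so every chosen label is
#' wrong), and records the true pairing between the original sample and the
#' label its data now carries.
#'
#' @param expr an [omics_matrix()].
#' @param n_swaps number of labels to permute (0 = identity; 2 = one
#'   transposition).  Must not exceed the number of samples.
#' @param seed integer seed.
#' @return A list with `expr` (relabeled matrix) and `pairing`, a data frame
#'   with columns `true_sample` (whose data the column holds) and
#'   `expr_label` (the label it now carries).
#' @export
shuffle_samples <- function(expr, n_swaps, seed = 1) {
  stopifnot(inherits(expr, "omics_matrix"))
  n <- ncol(expr$values)
  if (n_swaps > n) stop("'n_swaps' exceeds the number of samples")
  set.seed(seed)
  old <- colnames(expr$values)
  new <- old
  if (n_swaps >= 2) {
    idx <- sample(n, n_swaps)
    new[idx] <- old[idx][c(seq_len(n_swaps)[-1], 1L)]  # cyclic shift
  }
  v <- expr$values
  colnames(v) <- new
  out <- omics_matrix(v, expr$modality, group = setNames(unname(expr$group), new),
                      adjusted = expr$adjusted)
  list(expr = out,
       pairing = data.frame(true_sample = old, expr_label = new,
                            stringsAsFactors = FALSE))
}
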