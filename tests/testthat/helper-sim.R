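# Scaled-down study conditions for fast unit tests; the full default config
# is exercised in the acceptance suite.

small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 60, probes_per_gene = 2, n_key_regulators = 2,
               downstream_counts = c(10L, 6L, 2L, 1L, 1L),
               frac_model2 = 0.2, n_confounded = 2, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# a config with no planted structure at all: the global null
null_config <- function(seed = 1, n_ctrl = 52, n_copd = 100, n_genes = 100) {
  sim_config(n_ctrl = n_ctrl, n_copd = n_copd, n_genes = n_genes,
             n_key_regulators = 0, downstream_counts = integer(0),
             frac_model2 = 0, n_confounded = 0, hypermeth_shift = 0,
             cis_effect_sd = 0, trait_noise_sd = 1, seed = seed)
}

# simulate + adjust covariates, the state in which association/causality run
sim_adjusted <- function(config) {
  sim <- simulate_methexpr(config)
  sim$ann <- map_probes(sim$probes, sim$genes)
  sim$meth_adj <- adjust_covariates(sim$meth, sim$covariates)
  sim$expr_adj <- adjust_covariates(sim$expr, sim$covariates)
  sim
}

trio_key <- function(d) paste(d$probe_id, d$trans_gene)
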