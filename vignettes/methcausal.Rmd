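---
title: "Methods: trio causality between promoter methylation and expression"
author: "methcausal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio causality between promoter methylation and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcausal)
```

## The question and the model

In a two-group cohort (here labelled CTRL and COPD) with paired promoter
methylation (beta values, M) and gene expression (E) on the same
individuals, we want to know which promoter-methylation changes *drive*
expression programs rather than merely accompany them. The unit of
inference is the anchored trio

* **M** — a methylation probe in gene *g*'s promoter,
* **C** — the expression of *g* itself (the probe's *cis* gene),
* **T** — the expression of some other gene (*trans*),

and the two causal chains under comparison are

* **Model I** — M → C → T: methylation alters *g*'s transcription, and
  *g*'s product (transcription factor, signalling protein, ...) alters T;
* **Model II** — T → M → C: the trans gene's product alters the methylation
  machinery at *g*'s promoter, which then moves C.

Both chains predict association between every pair, so associations alone
cannot orient them. What distinguishes them is *conditional independence*:
in a chain X → Z → Y, the ends are independent given the mediator. Model I
is accepted for a trio when

1. Spearman p(M, C) < `p_cis` (default 0.01),
2. Spearman p(C, T) < `p_assoc` (default 10⁻⁴),
3. the Spearman association of M with the OLS residuals of T on C is *not*
   significant (p > `p_indep`, default 0.01);

Model II mirrors this with the chain reversed (p(T, M) < `p_assoc`, and T
independent of the residuals of C on M). A trio can satisfy neither
(`none`). If it satisfies both, the chain with the larger
conditional-independence p-value — the stronger mediation evidence — wins
and the trio is flagged `ambiguous`; a tie rule is needed because the two
chains are not mutually exclusive hypotheses at finite n.

All associations are Spearman (rank) correlations with the t approximation
`t = rho * sqrt((n-2)/(1-rho^2))`; only the mediation regression is ordinary
least squares on raw values. The package assumes monotone (not necessarily
linear) marginal relationships and an approximately linear mediation; it
makes no normality assumption for the association tests.

### Why covariate adjustment must precede the causality test

Expression carries covariate effects (age, sex, smoking). Consider a true
Model-I chain M → C → T where age also affects both C and T. Conditioning
on C — a *collider* child of M and age — induces dependence between M and
age, and through age a spurious M–T dependence given C. The
conditional-independence test then rejects genuine Model-I chains. Removing
covariates first (per feature: OLS on the covariate design, keep mean plus
residuals, `adjust_covariates()`) closes this backdoor; `run_pipeline()`
therefore adjusts both matrices before any association or causality test.
Feature means are preserved exactly and the operation is idempotent.

### Identifiability: the probes must be faithful

Orienting M → C against T → M → C hinges on an asymmetry: when the
methylation latent is the true mediator (Model II), conditioning on the
*measured* probe must actually block the path. If probe-level measurement
noise is comparable to the biological methylation variance, the measured M
is a poor proxy of the mediator, residual confounding leaks through, and
both directions land in the ambiguous zone. The simulator therefore
separates `probe_noise_sd` (measurement noise around the gene-level
promoter latent, default 0.25 on the logit scale — beta estimates from
tiling arrays are smoothed over neighbouring probes and are precise
relative to the unit-variance biological signal) from `noise_sd` (residual
expression noise, default 0.6). The converse is also required: the cis
expression must be a *noisier* readout of the promoter state than the
probes are, otherwise conditioning on C blocks the M–T path of a reversed
chain almost as well as conditioning on M would, and Model II cannot be
told from Model I. These two defaults encode the identifiability regime the
trio test needs; they are properties of the planted study conditions, not
tuning knobs of the test itself.

## Permutation false-discovery rates

Every discovery count is calibrated by permutation:

* differential methylation/expression — group labels are permuted
  (preserving group sizes), 100 times by default;
* association, causality and trait signatures — the *whole expression
  matrix* has its sample columns permuted (methylation untouched), 5 times
  by default, and the full detection (cis anchoring → trans scan →
  classification) is re-run on each permuted matrix.

`FDR = mean(permuted count) / observed count`, clipped to [0, 1], reported
as undefined when nothing is observed. The arithmetic is exposed in
`fdr_report()`: 518 mean permuted calls over 362,095 observed gives 0.0014.

A subtlety worth knowing: permuting the expression matrix also destroys the
*cis anchors*, so the permuted runs scan fewer candidate trios than the
observed run whenever real cis structure exists. The estimate is therefore
calibrated for the global null (no methylation–expression association at
all); in a cohort with strong cis biology but no trans signal it
understates the FDR. The null-calibration test in the acceptance suite
uses a fully null simulation (`cis_effect_sd = 0`) for exactly this reason,
and runs the causality stage at loosened thresholds (cis anchor 0.1–0.2,
chain association 0.05) solely so that the null produces countable calls —
under the null the FDR estimate is near 1 at *any* threshold, so the choice
of threshold does not change what the test demonstrates.

## Key regulators and the degree distribution

Model-I calls are aggregated per cis gene (`summarize_regulators()`): the
downstream set is the union of trans genes over all of the gene's probes.
The distribution of downstream counts is heavy-tailed — approximately
linear in a log-log frequency plot (`scale_free_fit()`, least squares of
log10 frequency on log10 count) — and key regulators are genes whose count
strictly exceeds mean + `k_sd` · SD (sample SD, n−1) of the counts over all
genes with at least one downstream target (`key_regulators()`, default
`k_sd = 2`, with the stricter 3 SD variant available). Genes that never
anchor a causal trio are excluded from the population: including structural
zeros would deflate the mean far below the regulating population and make
the threshold arbitrary; the switch is a one-line change if the alternative
convention is wanted. The mirrored analysis on Model-II calls (grouping by
the source expression gene) exposes hubs of expression→methylation
regulation.

## Severity traits and the overlap screens

Five severity traits (DLCO, BODE, FEV1pp, FEV1/FVC, emphysema%) enter two
screens:

* `regulator_trait_screen()` — Spearman correlation of each key regulator's
  mean promoter beta with each trait (pairwise-complete, minimum 10
  observations), reporting regulators significant for *all five* traits at
  p < 0.05;
* `downstream_signature_screen()` — upper-tail hypergeometric overlap
  (`overlap_test()`, identical to one-sided Fisher) of each regulator's
  downstream set with each trait's expression signature (genes correlated
  with the trait at p < 0.01), again requiring all five.

The universe for overlap tests is the set of genes in the expression matrix
after preprocessing; it is an explicit argument because overlap p-values
are meaningless without a stated universe. Gene-set collections tested with
`geneset_collection_enrichment()` drop sets larger than 1,500 genes (on
their raw size, before universe intersection) as non-specific.

## The synthetic cohort

`simulate_methexpr()` generates the full input bundle with known truth.
Default study conditions: 52 CTRL + 100 COPD samples; 500 genes on one
synthetic chromosome (TSS every 100 kb, probes within ±5 kb of the TSS, 2
probes per gene, 60% of promoters flagged as CpG islands).

* **Methylation.** Each gene has a latent promoter methylation level
  (logit scale, unit biological variance) shifted upward by
  `hypermeth_shift` (default 0.5) in the COPD group for island promoters;
  probes are inverse-logit transforms of the latent plus a probe offset and
  measurement noise, keeping beta in [0, 1].
* **Cis links.** Every gene that is not itself a planted trans target
  carries a cis coefficient of magnitude `cis_effect_sd` (default 1),
  positive with probability `frac_positive_cis` (default 0.45 — promoter
  methylation silences slightly more often than it activates, but both
  signs are common).
* **Model-I structure.** 5 hub regulators with 80, 70, 60, 50, 40
  downstream genes and 35 minor regulators with 1–5, a deterministic
  heavy-tailed degree list that respects the gene budget for every seed.
  Downstream genes are driven by their regulator's expression (±
  `trans_effect_sd`) and carry no cis term of their own, so planted chains
  are fully mediated.
* **Model-II structure.** A fraction `frac_model2` (default 0.05) of the
  chain count is reversed: a source gene's expression drives other genes'
  promoter methylation, which then moves their cis expression.
* **Confounded pairs.** `n_confounded` (default 10) partner genes are
  driven *directly* by another gene's methylation latent, bypassing its cis
  expression — trios whose M–T dependence no amount of conditioning on C
  explains away.
* **Covariates.** Age, sex and pack-years with per-gene coefficients of SD
  `covariate_effects` (default 0.3 each) on standardised covariates,
  expression only.
* **Traits.** Each of the five traits is a *differently* weighted sum
  (U(0, 1) weights) of the first hub's downstream expression — five
  clinical measures reflect different facets of one severity process — with
  DLCO, FEV1pp and FEV1/FVC falling and BODE and emphysema% rising in
  severity, plus noise (`trait_noise_sd`, default 0.5). Traits are missing
  at different rates (BODE near-complete, emphysema scored in the fewest
  patients), scaled by `trait_missing` (default 0.15), emulating clinical
  measurement patterns.

What the generator deliberately does **not** emulate: array probe-level
intensity noise models, batch effects, cell-type composition, genomic
correlation along the chromosome, or realistic demographic structure.
Passing tests on this cohort demonstrate that the *inference machinery*
recovers planted structure under its stated assumptions — not that those
assumptions hold in any particular real data set.

## Numerical conventions and degenerate inputs

* Ranks use average ties; |rho| = 1 gives p = 0; zero variance gives
  (rho 0, p 1); fewer than 5 complete pairs gives (rho NA, p 1, flagged).
* OLS residuals that are numerically zero (SD below 1e−10 of the response
  scale) mean perfect mediation: conditional-independence p = 1.
* Probe→gene assignment is strict (`< 10 kb`); equidistant ties go to the
  lexicographically smaller gene id and are flagged.
* BED intervals are 0-based half-open on disk, 1-based closed internally.
* Sample matching accepts a pair only if it is the mutual best in its row
  and column and its score exceeds the mean of the row's *mismatched*
  scores by 3 of their SDs; ties are dropped, never broken arbitrarily.
* Permutation streams are seeded; identical config and seed reproduce every
  output bit-for-bit.

## Problem sizes

The test suite validates the full default cohort (152 samples × 500 genes ×
1,000 probes) end-to-end, five such cohorts for the screen-specificity
checks, a 2,000-sample cohort for the large-n conditional-independence
property, and 100,000-draw permutation oracles for the Spearman
approximation; the whole suite runs in about a minute on one core. These
sizes were chosen so that every planted effect is comfortably powered while
the suite stays quick to iterate on.

## Known limitations

* **Forks masquerade as Model II.** A trio in which T is driven directly by
  the methylation latent (T ← m → C) has exactly the conditional
  independencies of the Model-II chain (T → m → C): both make C ⊥ T given
  M. Without an upstream anchor (an instrument for M), no conditional-
  independence test can separate them; such confounded trios are correctly
  *excluded from Model I* but are reported as Model II. Model-II calls
  should therefore be read as "methylation is the mediator between T and
  C", with the T → M arrow an assumption, not a conclusion.
* **Anchor asymmetry of the permutation null** (above): the FDR is
  calibrated against the no-association null, not against a cis-only null.
* **Screen specificity at small universes.** With ~80-gene downstream sets
  and ~85-gene signatures in a 500-gene universe, the five trait signatures
  share most of their genes, so the all-five hypergeometric screen at
  p < 0.05 behaves like a single 5% test per regulator; a random gene set
  then survives the screen for some regulator in roughly one dataset in
  ten. This is a property of the desk-scale simulation — with genome-scale
  universes and partially independent clinical signatures the joint chance
  rate is orders of magnitude smaller — and it is why screen survivors
  should be confirmed against external gene sets
  (`geneset_collection_enrichment()`) rather than taken alone.
* The matcher instantiates the published idea (profiles of the same
  individual correlate across omics) with one concrete rule
  (mutual-best + z ≥ 3 over sign-aligned cis features); exact fidelity to
  the original multi-assay procedure is not claimed.
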