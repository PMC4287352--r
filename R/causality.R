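## Trio causality test
##
## For a candidate trio (M = promoter methylation probe, C = the probe's cis
## gene expression, T = a trans gene expression) two causal chains are
## evaluated:
##
##   Model I :  M -> C -> T   (methylation drives trans expression via cis)
##   Model II:  T -> M -> C   (trans expression drives methylation)
##
## A chain is accepted when its links are associated and the ends are
## conditionally independent given the mediator: for Model I, T is regressed
## on C by OLS and the Spearman association of M with the residuals must be
## non-significant; for Model II, C is regressed on M and T must be
## unassociated with the residuals.  Confounded trios (a latent factor
## driving both M and T) fail both conditional-independence checks and are
## left unclassified.

#' Conditional independence given a putative mediator
#'
#' Direction `"I"` regresses the trans expression `t` on the cis expression
#' `c` (intercept + slope, OLS) and returns the Spearman p-value of the
#' methylation `m` against the residuals; direction `"II"` regresses `c` on
#' `m` and tests `t` against the residuals.  Zero-variance residuals
#' (perfect mediation) give `p = 1`.
#'
#' @param m,c,t numeric vectors over the same samples.
#' @param direction `"I"` or `"II"`.
#' @return Two-sided Spearman p-value of the end variable against the
#'   residuals; large values support the causal chain.
#' @export
conditional_independence <- function(m, c, t, direction = c("I", "II")) {
  direction <- match.arg(direction)
  if (direction == "I") {
    r <- ols_residuals(t, c)
    if (zero_residuals(r, t)) return(1)   # perfect mediation
    spearman_test(m, r)$p
  } else {
    r <- ols_residuals(c, m)
    if (zero_residuals(r, c)) return(1)
    spearman_test(t, r)$p
  }
}

# residuals that are numerically zero relative to the response scale mark an
# exactly mediated relationship
zero_residuals <- function(r, y) {
  sd(r) < 1e-10 * max(sd(y), 1e-300)
}

ols_residuals <- function(y, x) {
  fit <- lm.fit(cbind(1, x), y)
  fit$residuals
}

#' Default thresholds of the trio causality test
#'
#' `p_cis`: the M--C association must satisfy `p < p_cis`; `p_assoc`: the
#' association of the chain's driving link with the trans end (C--T for
#' Model I, T--M for Model II) must satisfy `p < p_assoc`; `p_indep`: the
#' conditional-independence p-value must exceed `p_indep`.
#'
#' @param p_cis,p_assoc,p_indep thresholds in (0, 1\].
#' @return A named list.
#' @export
causality_thresholds <- function(p_cis = 0.01, p_assoc = 1e-4, p_indep = 0.01) {
  stopifnot(p_cis > 0, p_cis <= 1, p_assoc > 0, p_assoc <= 1,
            p_indep >= 0, p_indep < 1)
  list(p_cis = p_cis, p_assoc = p_assoc, p_indep = p_indep)
}

#' Classify a single candidate trio
#'
#' Evaluates both causal chains on raw vectors.  Model I requires
#' `p(M,C) < p_cis`, `p(C,T) < p_assoc` and conditional independence of M
#' and T given C (`p > p_indep`); Model II requires `p(M,C) < p_cis`,
#' `p(T,M) < p_assoc` and conditional independence of C and T given M.  A
#' trio may satisfy neither (`model = "none"`); if it satisfies both, the
#' chain with the larger conditional-independence p-value (stronger
#' mediation evidence) wins and the trio is flagged `ambiguous`.
#'
#' @param m,c,t numeric vectors: methylation probe, cis gene expression,
#'   trans gene expression.
#' @param thresholds see [causality_thresholds()].
#' @return A one-row data frame with all five p-values
#'   (`p_cis`, `p_ct`, `p_trans`, `p_indep1`, `p_indep2`), the verdict
#'   `model` in `{"I", "II", "none"}` and the `ambiguous` flag.
#' @export
classify_trio <- function(m, c, t, thresholds = causality_thresholds()) {
  th <- thresholds
  bad <- function(v) length(unique(v[is.finite(v)])) < 2L
  if (bad(m) || bad(c) || bad(t)) {
    return(data.frame(p_cis = 1, p_ct = 1, p_trans = 1, p_indep1 = NA_real_,
                      p_indep2 = NA_real_, model = "none", ambiguous = FALSE,
                      reason = "degenerate input", stringsAsFactors = FALSE))
  }
  p_mc <- spearman_test(m, c)$p
  p_ct <- spearman_test(c, t)$p
  p_mt <- spearman_test(m, t)$p
  p_i1 <- conditional_independence(m, c, t, "I")
  p_i2 <- conditional_independence(m, c, t, "II")
  ok1 <- p_mc < th$p_cis && p_ct < th$p_assoc && p_i1 > th$p_indep
  ok2 <- p_mc < th$p_cis && p_mt < th$p_assoc && p_i2 > th$p_indep
  model <- if (ok1 && ok2) {
    if (p_i1 >= p_i2) "I" else "II"
  } else if (ok1) "I" else if (ok2) "II" else "none"
  data.frame(p_cis = p_mc, p_ct = p_ct, p_trans = p_mt, p_indep1 = p_i1,
             p_indep2 = p_i2, model = model, ambiguous = ok1 && ok2,
             reason = NA_character_, stringsAsFactors = FALSE)
}

classify_candidates <- function(candidates, meth, expr,
                                thresholds = causality_thresholds()) {
  if (nrow(candidates) == 0L) {
    out <- data.frame(probe_id = character(0), cis_gene = character(0),
                      trans_gene = character(0), p_cis = numeric(0),
                      p_ct = numeric(0), p_trans = numeric(0),
                      p_indep1 = numeric(0), p_indep2 = numeric(0),
                      model = character(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  mv <- meth$values
  ev <- expr$values
  res <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    res[[i]] <- classify_trio(mv[candidates$probe_id[i], ],
                              ev[candidates$cis_gene[i], ],
                              ev[candidates$gene_id[i], ], thresholds)
  }
  res <- do.call(rbind, res)
  cbind(data.frame(probe_id = candidates$probe_id,
                   cis_gene = candidates$cis_gene,
                   trans_gene = candidates$gene_id,
                   stringsAsFactors = FALSE),
        res[, setdiff(colnames(res), "reason")])
}

#' Run the causality test over all candidate trios, with permutation FDR
#'
#' Derives candidate trios (cis anchoring at `p_cis_anchor`, trans scan at
#' `p_trans`), classifies each, and estimates per-model FDRs by rerunning
#' candidate derivation and classification on expression matrices whose
#' sample columns were randomly permuted (methylation untouched).
#'
#' @param meth,expr matched [omics_matrix()]s.
#' @param annotation mapped probe annotation.
#' @param p_cis_anchor cis anchoring threshold for candidate generation.
#' @param p_trans trans scan threshold for candidate generation.
#' @param thresholds classification thresholds ([causality_thresholds()]).
#' @param n_perm number of expression permutations (default 5).
#' @param seed integer seed.
#' @return A list with `trios` (classified trio table), `candidates`
#'   (number of candidate trios), and `fdr`, a list of [fdr_report()]s for
#'   models `"I"` and `"II"`.
#' @export
run_causality <- function(meth, expr, annotation, p_cis_anchor = 0.01,
                          p_trans = 1e-5,
                          thresholds = causality_thresholds(),
                          n_perm = 5, seed = 1) {
  derive <- function(e) {
    cis <- find_cis_pairs(meth, e, annotation, p_cis_anchor)
    if (nrow(cis) == 0L) return(empty_pairs("trans"))
    find_trans_pairs(meth, e, annotation, p_trans, cis)
  }
  candidates <- derive(expr)
  trios <- classify_candidates(candidates, meth, expr, thresholds)
  obs1 <- sum(trios$model == "I")
  obs2 <- sum(trios$model == "II")
  set.seed(seed)
  perm1 <- perm2 <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    pe <- permute_expr_columns(expr)
    pcand <- derive(pe)
    ptr <- classify_candidates(pcand, meth, pe, thresholds)
    perm1[b] <- sum(ptr$model == "I")
    perm2[b] <- sum(ptr$model == "II")
  }
  list(trios = trios, candidates = nrow(candidates),
       fdr = list(I = fdr_report(p_trans, obs1, perm1),
                  II = fdr_report(p_trans, obs2, perm2)))
}
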