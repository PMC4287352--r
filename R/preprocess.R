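#' Map methylation probes to the nearest transcription start site
#'
#' Each probe is assigned to the gene (on the same chromosome) whose TSS is
#' closest, provided the distance is strictly below `max_dist`; otherwise it
#' stays unassigned.  The recorded distance is strand-signed: positive means
#' the probe lies downstream of the TSS in the gene's reading direction.
#' A probe exactly equidistant from two TSSs is assigned to the
#' lexicographically smaller `gene_id` and flagged in the `tie` column.
#'
#' @param probes probe annotation data frame (see [read_probe_bed()]).
#' @param genes gene annotation data frame (see [read_gene_table()]).
#' @param max_dist assignment radius in bp (strict `<`, default 10 kb).
#' @return The probe annotation with `gene_id`, `tss_distance` and `tie`
#'   filled in.
#' @export
map_probes <- function(probes, genes, max_dist = 10000) {
  probes$gene_id <- NA_character_
  probes$tss_distance <- NA_integer_
  probes$tie <- FALSE
  for (chr in unique(probes$chromosome)) {
    gi <- genes[genes$chromosome == chr, , drop = FALSE]
    pi <- which(probes$chromosome == chr)
    if (nrow(gi) == 0L || length(pi) == 0L) next
    ord <- order(gi$tss, gi$gene_id)
    gi <- gi[ord, , drop = FALSE]
    pos <- probes$position[pi]
    # candidate neighbours around each probe in TSS order
    idx <- findInterval(pos, gi$tss)
    for (k in seq_along(pi)) {
      # window of neighbours covers equidistant and equal-TSS genes
      cand <- unique(pmin(pmax(idx[k] + (-1L:2L), 1L), nrow(gi)))
      d <- abs(pos[k] - gi$tss[cand])
      best <- which(d == min(d))
      if (min(d) >= max_dist) next
      cand <- cand[best]
      tie <- length(cand) > 1L
      g <- gi[cand[order(gi$gene_id[cand])][1L], ]
      p <- pi[k]
      probes$gene_id[p] <- g$gene_id
      signed <- pos[k] - g$tss
      probes$tss_distance[p] <- if (g$strand == "+") signed else -signed
      probes$tie[p] <- tie
    }
  }
  probes
}

#' Remove covariate effects, keeping feature means
#'
#' Per feature, fits ordinary least squares on the covariate design
#' (categorical covariates dummy-coded) and returns the feature mean plus the
#' residuals, so that downstream analyses see covariate-free variation on the
#' original scale.  Feature means are preserved exactly and the operation is
#' idempotent.  Collinear design columns are dropped with a warning.
#'
#' @param x an [omics_matrix()].
#' @param covariates data frame with `sample_id` plus covariate columns; must
#'   cover every sample of `x`.
#' @return An [omics_matrix()] with the same dimensions, marked `adjusted`.
#' @export
adjust_covariates <- function(x, covariates) {
  stopifnot(inherits(x, "omics_matrix"))
  ids <- sample_ids(x)
  miss <- setdiff(ids, covariates$sample_id)
  if (length(miss) > 0L)
    stop("covariates missing for sample: ", miss[1L])
  cv <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
  cv$sample_id <- NULL
  design <- stats::model.matrix(~ ., data = cv)
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) {
    dropped <- colnames(design)[qrx$pivot[(qrx$rank + 1L):ncol(design)]]
    warning("rank-deficient covariate design; dropping: ",
            paste(dropped, collapse = ", "))
  }
  resid <- t(qr.resid(qrx, t(x$values)))
  out <- rowMeans(x$values) + resid
  dimnames(out) <- dimnames(x$values)
  omics_matrix(out, x$modality, group = x$group, adjusted = TRUE)
}

#' Filter mapped probes
#'
#' Retains probes with an assigned gene, optionally restricted to CpG-island
#' probes, to a window around the TSS, and to genes carrying a minimum
#' number of (retained) probes.
#'
#' @param probes mapped probe annotation (see [map_probes()]).
#' @param require_island keep only CpG-island probes.
#' @param tss_window optional bp radius: keep probes with
#'   `abs(tss_distance) < tss_window`.
#' @param min_probes_per_gene optional minimum probe count per gene after the
#'   other filters.
#' @return The filtered probe annotation.
#' @export
filter_probes <- function(probes, require_island = FALSE, tss_window = NULL,
                          min_probes_per_gene = NULL) {
  keep <- !is.na(probes$gene_id)
  if (require_island) keep <- keep & probes$cpg_island
  if (!is.null(tss_window)) keep <- keep & abs(probes$tss_distance) < tss_window
  out <- probes[keep, , drop = FALSE]
  if (!is.null(min_probes_per_gene)) {
    cnt <- table(out$gene_id)
    out <- out[cnt[out$gene_id] >= min_probes_per_gene, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

row_t_test <- function(values, g1, g2, var_equal = TRUE) {
  x1 <- values[, g1, drop = FALSE]
  x2 <- values[, g2, drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  zero <- !is.finite(se) | se == 0
  t[zero] <- NA_real_
  p[zero] <- 1
  list(mean1 = m1, mean2 = m2, t = t, p = p, zero_var = zero)
}

#' Two-group differential analysis
#'
#' Per-feature two-sample t-test (pooled variance by default, Welch behind
#' `var_equal = FALSE`) of COPD versus CTRL.  Direction is the sign of the
#' COPD minus CTRL mean difference: `hyper`/`hypo` for methylation,
#' `up`/`down` for expression.  Features with zero pooled variance get
#' `p = 1` and an undefined direction.
#'
#' @param x an [omics_matrix()] with group labels, or group supplied via
#'   `groups`.
#' @param groups optional per-sample labels overriding `x$group`.
#' @param var_equal pooled-variance t-test when `TRUE` (default).
#' @return A data frame with columns `feature_id`, `mean_ctrl`, `mean_copd`,
#'   `t`, `p`, `direction`.
#' @export
differential <- function(x, groups = NULL, var_equal = TRUE) {
  stopifnot(inherits(x, "omics_matrix"))
  if (is.null(groups)) groups <- x$group
  if (is.null(groups)) stop("group labels required")
  g1 <- which(groups == "COPD")
  g2 <- which(groups == "CTRL")
  if (length(g1) < 2L || length(g2) < 2L)
    stop("need >=2 samples per group")
  r <- row_t_test(x$values, g1, g2, var_equal)
  up <- if (x$modality == "methylation-beta") c("hyper", "hypo") else c("up", "down")
  dir <- ifelse(r$mean1 > r$mean2, up[1L], up[2L])
  dir[r$zero_var | r$mean1 == r$mean2] <- NA_character_
  data.frame(feature_id = feature_ids(x), mean_ctrl = r$mean2,
             mean_copd = r$mean1, t = r$t, p = r$p, direction = dir,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation FDR report
#'
#' The common container for permutation-based false discovery rates:
#' `fdr = mean(permuted counts) / observed count`, clipped to \[0, 1\];
#' undefined (`NA`) when nothing is observed.
#'
#' @param threshold the p-value threshold the counts refer to.
#' @param observed number of discoveries in the observed data.
#' @param permuted integer vector of per-permutation discovery counts.
#' @return A list of class `fdr_report` with fields `threshold`, `observed`,
#'   `permuted`, `mean_permuted`, `fdr`.
#' @export
#' @examples
#' fdr_report(0.01, observed = 362095, permuted = 518)$fdr  # 0.00143...
fdr_report <- function(threshold, observed, permuted) {
  mean_perm <- if (length(permuted) > 0) mean(permuted) else NA_real_
  fdr <- if (is.na(observed) || observed == 0) NA_real_
         else min(1, max(0, mean_perm / observed))
  structure(list(threshold = threshold, observed = observed,
                 permuted = permuted, mean_permuted = mean_perm, fdr = fdr),
            class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf("permutation FDR at threshold %g: observed %d, mean permuted %.2f, FDR %s\n",
              x$threshold, x$observed, x$mean_permuted,
              if (is.na(x$fdr)) "undefined" else signif(x$fdr, 2)))
  invisible(x)
}

#' Permutation FDR for differential analysis
#'
#' Permutes the group labels (preserving group sizes), recomputes the
#' per-feature t-tests, and estimates the FDR at `p_threshold` as the mean
#' permuted discovery count over the observed count.
#'
#' @inheritParams differential
#' @param p_threshold significance threshold on the t-test p-value.
#' @param n_perm number of label permutations (default 100).
#' @param seed integer seed for the permutation stream.
#' @return An [fdr_report()].
#' @export
permutation_fdr_differential <- function(x, groups = NULL, p_threshold = 0.01,
                                         n_perm = 100, seed = 1,
                                         var_equal = TRUE) {
  stopifnot(inherits(x, "omics_matrix"))
  if (is.null(groups)) groups <- x$group
  obs <- differential(x, groups, var_equal)
  n_obs <- sum(obs$p < p_threshold)
  set.seed(seed)
  perm <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    pg <- sample(groups)
    r <- row_t_test(x$values, which(pg == "COPD"), which(pg == "CTRL"),
                    var_equal)
    perm[b] <- sum(r$p < p_threshold)
  }
  fdr_report(p_threshold, n_obs, perm)
}
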