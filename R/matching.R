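#' Iteratively match methylation samples to expression samples
#'
#' Cross-omics sample alignment in the spirit of MODMatcher: the cis
#' methylation--expression structure of the cohort is strong enough that a
#' sample's methylation profile over cis probes correlates with the
#' expression profile of the *same individual* far more than with any other
#' sample.  The procedure alternates between (1) detecting cis probe--gene
#' pairs at Spearman `p < p_cis` under the current pairing and (2) scoring
#' every (methylation sample, expression sample) combination by the
#' correlation of their sign-aligned, rank-standardised profiles over those
#' pairs.  A pair is accepted when it is the mutual best match in its row
#' and column and its score exceeds the row mean by `z_min` row standard
#' deviations; everything else is dropped as ambiguous.  Iteration stops
#' when the mapping no longer changes or after `max_iter` rounds.
#'
#' @param meth,expr [omics_matrix()]s; their column names are the nominal
#'   sample labels, and shared labels seed the first iteration (at least 20
#'   required).
#' @param annotation mapped probe annotation (see [map_probes()]).
#' @param p_cis Spearman threshold for the cis pairs used as matching
#'   features (default 0.01).
#' @param max_iter maximum alignment iterations (default 25).
#' @param z_min row z-score a match must reach (default 3).
#' @return A list of class `match_report`: `mapping` (named character
#'   vector, methylation sample -> expression sample), `score` (z-score per
#'   mapped pair), `iterations`, `dropped` (data frame of unmatched samples
#'   with reasons), and `n_cis_features` used in the final round.
#' @export
match_samples <- function(meth, expr, annotation, p_cis = 0.01, max_iter = 25,
                          z_min = 3) {
  stopifnot(inherits(meth, "omics_matrix"), inherits(expr, "omics_matrix"))
  mset <- sample_ids(meth)
  eset <- sample_ids(expr)
  shared <- intersect(mset, eset)
  if (length(shared) < 20L)
    stop("need >= 20 shared nominal samples to seed the matching")
  ann <- annotation[!is.na(annotation$gene_id) &
                    annotation$probe_id %in% feature_ids(meth) &
                    annotation$gene_id %in% feature_ids(expr), , drop = FALSE]
  pairing <- setNames(shared, shared)   # meth sample -> expr sample

  zm_all <- rank_standardize(meth$values[ann$probe_id, , drop = FALSE])
  ze_all <- rank_standardize(expr$values[ann$gene_id, , drop = FALSE])

  iterations <- 0L
  n_cis <- 0L
  score <- NULL
  repeat {
    iterations <- iterations + 1L
    ## (1) cis features under the current pairing
    mv <- meth$values[ann$probe_id, names(pairing), drop = FALSE]
    ev <- expr$values[ann$gene_id, unname(pairing), drop = FALSE]
    rho <- spearman_rho_paired(mv, ev)
    p <- spearman_p(rho, length(pairing))
    sel <- which(p < p_cis)
    n_cis <- length(sel)
    if (n_cis == 0L)
      stop("no cis probe-gene pairs detected at p < ", p_cis,
           "; the cis signal is too weak to match samples")
    ## (2) all-vs-all profile scores over the selected pairs, expression
    ## sign-aligned so positive and negative cis links reinforce each other
    zm <- zm_all[sel, , drop = FALSE]
    ze <- ze_all[sel, , drop = FALSE] * sign(rho[sel])
    score <- cor(zm, ze)   # meth samples x expr samples
    ## (3) mutual-best with row z-score guard; ties are dropped
    new_pairing <- character(0)
    zscore <- numeric(0)
    dropped <- data.frame(sample = character(0), side = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
    row_best <- apply(score, 1L, which_unique_max)
    col_best <- apply(score, 2L, which_unique_max)
    for (i in seq_along(mset)) {
      j <- row_best[i]
      reason <- NULL
      if (is.na(j)) {
        reason <- "ambiguous best match (tie)"
      } else if (is.na(col_best[j]) || col_best[j] != i) {
        reason <- "not mutual best"
      } else {
        # candidate compared against the row's mismatched scores only
        z <- (score[i, j] - mean(score[i, -j])) / sd(score[i, -j])
        if (z < z_min) reason <- sprintf("match z-score %.2f < %g", z, z_min)
      }
      if (is.null(reason)) {
        new_pairing[mset[i]] <- eset[j]
        zscore[mset[i]] <- z
      } else {
        dropped <- rbind(dropped, data.frame(sample = mset[i], side = "meth",
                                             reason = reason,
                                             stringsAsFactors = FALSE))
      }
    }
    unmatched_expr <- setdiff(eset, unname(new_pairing))
    if (length(unmatched_expr) > 0L)
      dropped <- rbind(dropped,
                       data.frame(sample = unmatched_expr, side = "expr",
                                  reason = "no mutual-best methylation sample",
                                  stringsAsFactors = FALSE))
    same <- identical(sort(names(new_pairing)), sort(names(pairing))) &&
      all(new_pairing[sort(names(new_pairing))] == pairing[sort(names(pairing))])
    pairing <- new_pairing
    if (length(pairing) == 0L)
      stop("all samples dropped during matching; signal too weak")
    if (same || iterations >= max_iter) break
  }
  structure(list(mapping = pairing, score = zscore, iterations = iterations,
                 dropped = dropped, n_cis_features = n_cis),
            class = "match_report")
}

# index of the unique maximum, NA when the top value is tied
which_unique_max <- function(v) {
  m <- max(v)
  w <- which(v >= m - 1e-12)
  if (length(w) == 1L) w else NA_integer_
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report: %d matched pairs in %d iteration(s), %d dropped (%d cis features)\n",
              length(x$mapping), x$iterations, nrow(x$dropped),
              x$n_cis_features))
  invisible(x)
}

#' Apply a match report to a pair of matrices
#'
#' Subsets both matrices to the matched samples and relabels the expression
#' columns with their methylation partner's sample id, so that downstream
#' stages see identically ordered, identically named samples.
#'
#' @param meth,expr [omics_matrix()]s given to [match_samples()].
#' @param report the resulting `match_report`.
#' @return A list with aligned `meth` and `expr` matrices.
#' @export
apply_matching <- function(meth, expr, report) {
  ms <- names(report$mapping)
  es <- unname(report$mapping)
  m2 <- subset_omics(meth, samples = ms)
  v <- expr$values[, es, drop = FALSE]
  colnames(v) <- ms
  e2 <- omics_matrix(v, expr$modality, group = m2$group, adjusted = expr$adjusted)
  list(meth = m2, expr = e2)
}
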