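## cis / trans association scans
##
## Associations between promoter methylation and expression are Spearman
## throughout.  A cis pair tests a probe against its own assigned gene; a
## trans pair tests a cis-anchored probe against every other gene.  The
## trans scan emits candidate trios (probe, cis gene, trans gene) for the
## causality test.

#' Find cis methylation--expression pairs
#'
#' One Spearman test per mapped probe against its assigned gene's expression;
#' pairs with `p < p_max` are retained.  Unmapped probes, and probes whose
#' gene has no expression row, are never tested.
#'
#' @param meth,expr [omics_matrix()]s over the same samples (same order).
#' @param annotation mapped probe annotation (see [map_probes()]).
#' @param p_max retention threshold on the Spearman p-value (default 0.01).
#' @return A data frame of class `association_pairs` with columns
#'   `probe_id`, `gene_id`, `rho`, `p`, `relation = "cis"`.
#' @export
find_cis_pairs <- function(meth, expr, annotation, p_max = 0.01) {
  check_same_samples(meth, expr)
  ann <- annotation[!is.na(annotation$gene_id) &
                    annotation$probe_id %in% feature_ids(meth) &
                    annotation$gene_id %in% feature_ids(expr), , drop = FALSE]
  if (nrow(ann) == 0L)
    return(empty_pairs("cis"))
  n <- ncol(meth$values)
  rho <- spearman_rho_paired(meth$values[ann$probe_id, , drop = FALSE],
                             expr$values[ann$gene_id, , drop = FALSE])
  p <- spearman_p(rho, n)
  keep <- p < p_max
  out <- data.frame(probe_id = ann$probe_id[keep], gene_id = ann$gene_id[keep],
                    rho = rho[keep], p = p[keep],
                    relation = rep("cis", sum(keep)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("association_pairs", "data.frame")
  out
}

#' Find trans pairs anchored on cis-regulated probes
#'
#' Tests only probes present in `cis_anchor` against every expression gene
#' other than the probe's own assigned gene, retaining `p < p_max`.  Each
#' retained pair defines a candidate trio (probe, cis gene, trans gene) for
#' the causality test.
#'
#' @inheritParams find_cis_pairs
#' @param p_max retention threshold (default 1e-5).
#' @param cis_anchor cis pairs from [find_cis_pairs()]; must be non-empty.
#' @param min_trans_distance optional bp guard: skip genes whose TSS is
#'   within this distance of the probe (same chromosome), in case local
#'   correlation should not count as trans.
#' @param genes gene annotation; only needed with `min_trans_distance`.
#' @return An `association_pairs` data frame with columns `probe_id`,
#'   `gene_id` (trans gene), `cis_gene`, `rho`, `p`, `relation = "trans"`.
#' @export
find_trans_pairs <- function(meth, expr, annotation, p_max = 1e-5,
                             cis_anchor = NULL, min_trans_distance = NULL,
                             genes = NULL) {
  check_same_samples(meth, expr)
  if (is.null(cis_anchor) || nrow(cis_anchor) == 0L)
    stop("'cis_anchor' must be a non-empty cis pair table")
  probes <- unique(cis_anchor$probe_id)
  cis_gene <- setNames(cis_anchor$gene_id[match(probes, cis_anchor$probe_id)],
                       probes)
  n <- ncol(meth$values)
  gids <- feature_ids(expr)
  rho <- spearman_rho_matrix(meth$values[probes, , drop = FALSE], expr$values)
  p <- matrix(spearman_p(as.vector(rho), n), nrow(rho), ncol(rho),
              dimnames = dimnames(rho))
  # a probe is never tested against its own assigned gene
  own <- cbind(seq_along(probes), match(cis_gene[probes], gids))
  own <- own[!is.na(own[, 2L]), , drop = FALSE]
  p[own] <- 1
  if (!is.null(min_trans_distance)) {
    if (is.null(genes)) stop("'genes' required with 'min_trans_distance'")
    ppos <- annotation$position[match(probes, annotation$probe_id)]
    pchr <- annotation$chromosome[match(probes, annotation$probe_id)]
    for (i in seq_along(probes)) {
      near <- genes$chromosome == pchr[i] &
        abs(genes$tss - ppos[i]) < min_trans_distance
      p[i, match(genes$gene_id[near], gids)] <- 1
    }
  }
  hit <- which(p < p_max, arr.ind = TRUE)
  out <- data.frame(probe_id = probes[hit[, 1L]], gene_id = gids[hit[, 2L]],
                    cis_gene = unname(cis_gene[probes[hit[, 1L]]]),
                    rho = rho[hit], p = p[hit],
                    relation = rep("trans", nrow(hit)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$probe_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("association_pairs", "data.frame")
  out
}

empty_pairs <- function(relation) {
  out <- data.frame(probe_id = character(0), gene_id = character(0),
                    rho = numeric(0), p = numeric(0),
                    relation = character(0), stringsAsFactors = FALSE)
  if (relation == "trans") out$cis_gene <- character(0)
  class(out) <- c("association_pairs", "data.frame")
  out
}

check_same_samples <- function(meth, expr) {
  stopifnot(inherits(meth, "omics_matrix"), inherits(expr, "omics_matrix"))
  if (ncol(meth$values) != ncol(expr$values) ||
      !all(sample_ids(meth) == sample_ids(expr)))
    stop("methylation and expression matrices must carry the same samples ",
         "in the same order (run the matching stage first)")
}

#' Permutation FDR for cis/trans pair detection
#'
#' Each permutation applies one random permutation to the sample columns of
#' the whole expression matrix (methylation untouched), reruns the cis and
#' trans scans, and counts retained trans pairs.  The FDR is the mean
#' permuted count over the observed count.
#'
#' @inheritParams find_trans_pairs
#' @param p_cis cis anchoring threshold.
#' @param n_perm number of expression permutations (default 5).
#' @param seed integer seed.
#' @return A list with `pairs` (observed trans pairs) and `fdr`
#'   (an [fdr_report()]).
#' @export
permutation_fdr_pairs <- function(meth, expr, annotation, p_max = 1e-5,
                                  p_cis = 0.01, n_perm = 5, seed = 1) {
  cis <- find_cis_pairs(meth, expr, annotation, p_cis)
  obs <- if (nrow(cis) > 0)
    find_trans_pairs(meth, expr, annotation, p_max, cis) else empty_pairs("trans")
  set.seed(seed)
  perm <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    pe <- permute_expr_columns(expr)
    pc <- find_cis_pairs(meth, pe, annotation, p_cis)
    perm[b] <- if (nrow(pc) > 0)
      nrow(find_trans_pairs(meth, pe, annotation, p_max, pc)) else 0L
  }
  list(pairs = obs, fdr = fdr_report(p_max, nrow(obs), perm))
}

# permute the sample columns of an expression matrix while keeping the
# nominal sample ids in place (the permutation null of the pipeline)
permute_expr_columns <- function(expr) {
  v <- expr$values[, sample(ncol(expr$values)), drop = FALSE]
  colnames(v) <- sample_ids(expr)
  omics_matrix(v, expr$modality, group = expr$group, adjusted = expr$adjusted)
}
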