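## Phenotype-severity screens and gene-set overlap statistics
##
## Trait signatures are genes whose expression correlates (Spearman) with a
## severity trait; regulator downstream sets are then screened against those
## signatures by the upper-tail hypergeometric test.  A regulator whose
## downstream set overlaps every trait signature is the analysis' endpoint:
## a candidate master switch of disease severity.

#' Upper-tail hypergeometric overlap test
#'
#' Probability of drawing at least `k` reference genes when `|query|` genes
#' are drawn without replacement from a universe of `universe_size`
#' containing `|reference|` reference genes.  Equivalent to a one-sided
#' Fisher's exact test on the 2x2 table.
#'
#' @param query,reference character vectors of gene ids (or, for
#'   `overlap_test_counts`, the counts directly).
#' @param universe_size size of the analysis universe; must be at least
#'   `|query| + |reference| - k`.
#' @return A list with `k` (overlap), `n_query`, `n_reference`, `universe`,
#'   `expected` and `p`.
#' @export
overlap_test <- function(query, reference, universe_size) {
  q <- unique(query)
  r <- unique(reference)
  overlap_test_counts(length(intersect(q, r)), length(q), length(r),
                      universe_size)
}

#' @rdname overlap_test
#' @param k,n_query,n_reference overlap and set sizes.
#' @export
overlap_test_counts <- function(k, n_query, n_reference, universe_size) {
  if (universe_size < n_query + n_reference - k)
    stop("universe smaller than the union of the two sets")
  if (k > min(n_query, n_reference))
    stop("overlap exceeds a set size")
  p <- phyper(k - 1, n_reference, universe_size - n_reference, n_query,
              lower.tail = FALSE)
  list(k = k, n_query = n_query, n_reference = n_reference,
       universe = universe_size,
       expected = n_query * n_reference / universe_size, p = p)
}

#' Trait expression signatures with permutation FDR
#'
#' For each severity trait, correlates every gene's expression with the
#' trait (Spearman, pairwise-complete over samples with a non-missing trait
#' value) and collects genes with `p < p_max` into the trait's signature.
#' FDR per trait comes from `n_perm` whole-matrix expression column
#' permutations.  Traits observed in fewer than `min_n` samples yield an
#' empty, flagged signature.
#'
#' @param expr an [omics_matrix()].
#' @param phenotypes data frame with `sample_id` and one column per trait;
#'   missing values allowed.
#' @param p_max signature threshold (default 0.01).
#' @param n_perm expression permutations for the FDR (default 5).
#' @param seed integer seed.
#' @param min_n minimum number of non-missing samples per trait (default 10).
#' @return A list with `signatures` (named list of gene-id vectors), `fdr`
#'   (named list of [fdr_report()]s) and `flagged` (traits with too few
#'   observations).
#' @export
trait_signatures <- function(expr, phenotypes, p_max = 0.01, n_perm = 5,
                             seed = 1, min_n = 10) {
  traits <- setdiff(colnames(phenotypes), "sample_id")
  ev <- expr$values[, intersect(sample_ids(expr), phenotypes$sample_id),
                    drop = FALSE]
  ph <- phenotypes[match(colnames(ev), phenotypes$sample_id), , drop = FALSE]
  sig_count <- function(values, trait_values, return_genes = FALSE) {
    keep <- is.finite(trait_values)
    if (sum(keep) < min_n) return(if (return_genes) character(0) else NA_integer_)
    v <- values[, keep, drop = FALSE]
    rho <- spearman_rho_matrix(v, matrix(trait_values[keep], nrow = 1L))[, 1L]
    p <- spearman_p(rho, sum(keep))
    if (return_genes) rownames(values)[p < p_max] else sum(p < p_max)
  }
  signatures <- list()
  fdr <- list()
  flagged <- character(0)
  set.seed(seed)
  perm_cols <- replicate(n_perm, sample(ncol(ev)))
  for (tr in traits) {
    tv <- ph[[tr]]
    if (sum(is.finite(tv)) < min_n) {
      signatures[[tr]] <- character(0)
      fdr[[tr]] <- fdr_report(p_max, 0L, integer(0))
      flagged <- c(flagged, tr)
      next
    }
    signatures[[tr]] <- sig_count(ev, tv, return_genes = TRUE)
    perm <- integer(n_perm)
    for (b in seq_len(n_perm)) {
      pv <- ev[, perm_cols[, b], drop = FALSE]
      colnames(pv) <- colnames(ev)
      perm[b] <- sig_count(pv, tv)
    }
    fdr[[tr]] <- fdr_report(p_max, length(signatures[[tr]]), perm)
  }
  list(signatures = signatures, fdr = fdr, flagged = flagged)
}

#' Screen regulator promoter methylation against severity traits
#'
#' Summarises each regulator's promoter methylation as the mean beta over
#' its mapped probes (or tests each probe separately with
#' `probe_level = TRUE`, where any significant probe counts) and correlates
#' it with each trait (Spearman, pairwise-complete).  Reports the
#' regulator-by-trait rho/p tables and the regulators significant for
#' *every* trait.
#'
#' @param meth an [omics_matrix()] of beta values.
#' @param regulators character vector of regulator gene ids.
#' @param annotation mapped probe annotation.
#' @param phenotypes data frame with `sample_id` and trait columns.
#' @param p_max per-trait significance threshold (default 0.05).
#' @param probe_level if `TRUE`, a regulator passes a trait when any of its
#'   probes is significant.
#' @return A list with matrices `rho` and `p` (regulator x trait) and
#'   `all_traits`, the regulators significant for all traits.
#' @export
regulator_trait_screen <- function(meth, regulators, annotation, phenotypes,
                                   p_max = 0.05, probe_level = FALSE) {
  traits <- setdiff(colnames(phenotypes), "sample_id")
  ids <- intersect(sample_ids(meth), phenotypes$sample_id)
  mv <- meth$values[, ids, drop = FALSE]
  ph <- phenotypes[match(ids, phenotypes$sample_id), , drop = FALSE]
  rho <- p <- matrix(NA_real_, length(regulators), length(traits),
                     dimnames = list(regulators, traits))
  for (g in regulators) {
    pr <- annotation$probe_id[!is.na(annotation$gene_id) &
                              annotation$gene_id == g]
    pr <- intersect(pr, rownames(mv))
    if (length(pr) == 0L) next
    for (tr in traits) {
      tv <- ph[[tr]]
      if (probe_level) {
        tests <- lapply(pr, function(pp) spearman_test(mv[pp, ], tv))
        best <- which.min(vapply(tests, `[[`, 0, "p"))
        rho[g, tr] <- tests[[best]]$rho
        p[g, tr] <- tests[[best]]$p
      } else {
        s <- spearman_test(colMeans(mv[pr, , drop = FALSE]), tv)
        rho[g, tr] <- s$rho
        p[g, tr] <- s$p
      }
    }
  }
  all_traits <- if (nrow(p) > 0)
    rownames(p)[apply(p, 1L, function(v) all(is.finite(v) & v < p_max))]
  else character(0)
  list(rho = rho, p = p, all_traits = all_traits)
}

#' Screen regulator downstream sets against trait signatures
#'
#' Hypergeometric overlap of each regulator's downstream target set with
#' each trait signature, over a common gene universe.  The endpoint is the
#' set of regulators whose downstream genes overlap *every* trait signature
#' at `p < p_max`.
#'
#' @param summaries a `regulator_summary` (see [summarize_regulators()]).
#' @param signatures named list of trait signatures (gene-id vectors).
#' @param universe character vector of universe gene ids (typically all
#'   genes in the expression matrix).
#' @param p_max per-trait threshold (default 0.05).
#' @return A list with `p` (regulator x trait matrix; empty signatures give
#'   `p = 1`) and `all_traits` (regulators significant for every trait).
#' @export
downstream_signature_screen <- function(summaries, signatures, universe,
                                        p_max = 0.05) {
  regs <- names(summaries)
  traits <- names(signatures)
  p <- matrix(1, length(regs), length(traits),
              dimnames = list(regs, traits))
  nu <- length(unique(universe))
  for (g in regs) {
    dn <- intersect(summaries[[g]]$downstream, universe)
    if (length(dn) == 0L) next
    for (tr in traits) {
      sig <- intersect(signatures[[tr]], universe)
      if (length(sig) == 0L) next
      p[g, tr] <- overlap_test(dn, sig, nu)$p
    }
  }
  all_traits <- if (length(regs) > 0 && length(traits) > 0)
    rownames(p)[apply(p, 1L, function(v) all(v < p_max))] else character(0)
  list(p = p, all_traits = all_traits)
}

#' Enrichment of a query set against a gene-set collection
#'
#' Upper-tail hypergeometric test of the query against each set of the
#' collection, after intersecting every set with the universe.  Oversized
#' sets (more than `max_set_size` genes, deemed non-specific) are skipped.
#'
#' @param query character vector of gene ids (non-empty).
#' @param collection named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of universe gene ids.
#' @param max_set_size largest collection set tested (default 1500).
#' @return A data frame with one row per tested set: `set`, `set_size`,
#'   `overlap`, `expected`, `p`, ordered by `p`.
#' @export
geneset_collection_enrichment <- function(query, collection, universe,
                                          max_set_size = 1500) {
  query <- intersect(unique(query), universe)
  if (length(query) == 0L) stop("empty query set after universe intersection")
  nu <- length(unique(universe))
  rows <- lapply(names(collection), function(nm) {
    raw <- unique(collection[[nm]])
    # oversized sets are non-specific: removed on their raw size, before
    # restriction to the universe
    if (length(raw) > max_set_size) return(NULL)
    ref <- intersect(raw, universe)
    if (length(ref) == 0L) return(NULL)
    ot <- overlap_test(query, ref, nu)
    data.frame(set = nm, set_size = length(ref), overlap = ot$k,
               expected = ot$expected, p = ot$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
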