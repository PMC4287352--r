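#' Aggregate causal trios into per-gene downstream target sets
#'
#' For Model I the regulator is the cis gene: its downstream set is the union
#' of trans genes over all of its probes.  For Model II the regulator is the
#' source expression gene (the trio's trans side) and the downstream set
#' collects the genes whose methylation it controls (the trios' cis genes).
#'
#' @param trios classified trio table (see [run_causality()]).
#' @param model `"I"` or `"II"`.
#' @return A list of class `regulator_summary`: per gene, `gene_id`,
#'   `downstream` (character vector) and `n_downstream`, ordered by
#'   decreasing count.
#' @export
summarize_regulators <- function(trios, model = c("I", "II")) {
  model <- match.arg(model)
  tr <- trios[trios$model == model, , drop = FALSE]
  if (nrow(tr) == 0L) {
    return(structure(list(), class = "regulator_summary"))
  }
  if (model == "I") {
    sets <- split(tr$trans_gene, tr$cis_gene)
  } else {
    sets <- split(tr$cis_gene, tr$trans_gene)
  }
  sets <- lapply(sets, function(g) sort(unique(g)))
  sets <- sets[order(-lengths(sets), names(sets))]
  out <- lapply(names(sets), function(g)
    list(gene_id = g, downstream = sets[[g]], n_downstream = length(sets[[g]])))
  names(out) <- names(sets)
  structure(out, class = "regulator_summary")
}

#' @export
print.regulator_summary <- function(x, ...) {
  cat(sprintf("regulator_summary: %d regulating genes\n", length(x)))
  if (length(x) > 0) {
    cnt <- downstream_counts(x)
    cat("  downstream counts:", paste(head(cnt, 10), collapse = ", "),
        if (length(cnt) > 10) "...", "\n")
  }
  invisible(x)
}

#' Downstream-target counts of a regulator summary
#'
#' @param summaries a `regulator_summary` (see [summarize_regulators()]).
#' @return Named integer vector of unique downstream-target counts.
#' @export
downstream_counts <- function(summaries) {
  vapply(summaries, `[[`, integer(1), "n_downstream")
}

#' Key regulators by the mean + k SD rule
#'
#' A gene is a key regulator when its number of unique downstream targets
#' strictly exceeds the mean plus `k_sd` sample standard deviations of the
#' counts across regulating genes (genes with at least one downstream
#' target; zero-count genes never enter the population).
#'
#' @param summaries a `regulator_summary`.
#' @param k_sd number of standard deviations above the mean (2 by default;
#'   3 gives the stricter variant).
#' @return Character vector of key-regulator gene ids (possibly empty).
#' @export
key_regulators <- function(summaries, k_sd = 2) {
  cnt <- downstream_counts(summaries)
  cnt <- cnt[cnt >= 1]
  if (length(cnt) < 2L) return(character(0))
  thr <- mean(cnt) + k_sd * sd(cnt)
  names(cnt)[cnt > thr]
}

#' Scale-free (power-law) fit of the downstream-degree distribution
#'
#' Least-squares fit of `log10(number of genes with count d)` against
#' `log10(d)` over the observed counts `d >= 1`.  A scale-free degree
#' distribution is linear in this log-log plot with negative slope.
#'
#' @param summaries a `regulator_summary`, or a bare integer vector of
#'   counts.
#' @return A list with `slope`, `r_squared`, `n_points` and `defined`
#'   (`FALSE` when fewer than 5 distinct count values are observed).
#' @export
scale_free_fit <- function(summaries) {
  cnt <- if (inherits(summaries, "regulator_summary"))
    downstream_counts(summaries) else as.integer(summaries)
  cnt <- cnt[cnt >= 1]
  tab <- table(cnt)
  if (length(tab) < 5L)
    return(list(slope = NA_real_, r_squared = NA_real_,
                n_points = length(tab), defined = FALSE))
  d <- log10(as.numeric(names(tab)))
  f <- log10(as.numeric(tab))
  fit <- lm(f ~ d)
  list(slope = unname(coef(fit)[2L]),
       r_squared = summary(fit)$r.squared,
       n_points = length(tab), defined = TRUE)
}
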