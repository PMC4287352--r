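#' Feature-by-sample omics matrix
#'
#' The basic data carrier for both assays: a numeric matrix with features in
#' rows and samples in columns, a modality tag, and an optional per-sample
#' group label (`"CTRL"` / `"COPD"`).  Methylation values are beta values
#' (fraction methylated) and must lie in \[0, 1\]; expression values are on a
#' log-like additive scale and need only be finite.
#'
#' @param values numeric matrix, features x samples, with unique non-empty
#'   rownames (feature ids) and colnames (sample ids).
#' @param modality `"methylation-beta"` or `"expression"`.
#' @param group optional character/factor vector of per-sample group labels,
#'   length `ncol(values)`, or a named vector matched to sample ids.
#' @param adjusted logical; `TRUE` marks a matrix that has been covariate
#'   adjusted (adjusted beta values may step slightly outside \[0, 1\] and are
#'   exempt from the range check).
#'
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `modality`, `group`, `adjusted`.
#' @export
#' @examples
#' m <- matrix(runif(6), 2, 3, dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' om <- omics_matrix(m, "methylation-beta")
#' dim(om)
omics_matrix <- function(values, modality = c("expression", "methylation-beta"),
                         group = NULL, adjusted = FALSE) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (any(!is.finite(values)))
    stop("non-finite values in matrix")
  if (modality == "methylation-beta" && !adjusted) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("beta value outside [0,1] at feature '%s', sample '%s'",
                   rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
  }
  if (!is.null(group)) {
    if (!is.null(names(group))) {
      miss <- setdiff(colnames(values), names(group))
      if (length(miss) > 0L)
        stop("group labels missing for sample: ", miss[1L])
      group <- group[colnames(values)]
    }
    if (length(group) != ncol(values))
      stop("'group' must have one label per sample")
    group <- as.character(group)
    names(group) <- colnames(values)
  }
  structure(list(values = values, modality = modality, group = group,
                 adjusted = isTRUE(adjusted)),
            class = "omics_matrix")
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s%s]: %d features x %d samples\n",
              x$modality, if (x$adjusted) ", adjusted" else "",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$group)) {
    tb <- table(x$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset an omics matrix by features and/or samples
#'
#' @param x an [omics_matrix()].
#' @param features,samples character vectors of ids (or logical/integer
#'   indices); `NULL` keeps all.
#' @return An `omics_matrix` restricted to the requested rows/columns.
#' @export
subset_omics <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  g <- if (is.null(x$group)) NULL else x$group[colnames(v)]
  omics_matrix(v, x$modality, group = g, adjusted = x$adjusted)
}

sample_ids <- function(x) colnames(x$values)
feature_ids <- function(x) rownames(x$values)
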