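#' Spearman rank correlation with t-approximation p-value
#'
#' The association primitive used throughout the pipeline.  Ranks use average
#' ties; the two-sided p-value comes from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Positions where either vector is missing are dropped (pairwise-complete).
#'
#' Degenerate inputs are given deliberate conventions rather than errors:
#' `|rho| = 1` yields `p = 0`; zero variance in either vector yields
#' `rho = 0, p = 1`; fewer than 5 complete pairs yields `rho = NA, p = 1`
#' with `ok = FALSE`.
#'
#' @param x,y numeric vectors of equal length.
#' @return A list with `rho`, `p`, `n` (complete pairs used) and `ok`
#'   (`FALSE` when too few pairs remained).
#' @export
#' @examples
#' spearman_test(1:10, (1:10)^3)   # rho = 1, p = 0
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5L) return(list(rho = NA_real_, p = 1, n = n, ok = FALSE))
  if (sd(x) == 0 || sd(y) == 0) return(list(rho = 0, p = 1, n = n, ok = TRUE))
  rho <- cor(rank(x), rank(y))
  list(rho = rho, p = spearman_p(rho, n), n = n, ok = TRUE)
}

# two-sided p from the t approximation; vectorised over rho
spearman_p <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  p <- rep(1, length(rho))
  at <- abs(rho) < 1 & !is.na(rho)
  tt <- abs(rho[at]) * sqrt((n - 2) / (1 - rho[at]^2))
  p[at] <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  p[abs(rho) == 1 & !is.na(rho)] <- 0
  p[is.na(rho)] <- 1
  p
}

# rank rows (average ties) and standardise to mean 0, sd 1.
# zero-variance rows are returned as all-zero and reported in attr "constant".
rank_standardize <- function(m) {
  r <- t(apply(m, 1L, rank))
  if (nrow(m) == 1L) r <- matrix(r, nrow = 1L, dimnames = dimnames(m))
  mu <- rowMeans(r)
  s <- sqrt(rowSums((r - mu)^2) / (ncol(r) - 1L))
  const <- s == 0
  s[const] <- 1
  z <- (r - mu) / s
  z[const, ] <- 0
  attr(z, "constant") <- const
  z
}

# all-pairs Spearman rho between rows of X and rows of Y (same samples).
# Returns a features_x by features_y matrix; zero-variance rows give rho 0.
spearman_rho_matrix <- function(x, y) {
  stopifnot(ncol(x) == ncol(y))
  n <- ncol(x)
  zx <- rank_standardize(x)
  zy <- rank_standardize(y)
  tcrossprod(zx, zy) / (n - 1L)
}

# paired Spearman rho between row i of X and row i of Y
spearman_rho_paired <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  n <- ncol(x)
  zx <- rank_standardize(x)
  zy <- rank_standardize(y)
  rowSums(zx * zy) / (n - 1L)
}
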