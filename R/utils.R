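#' @importFrom stats median quantile sd cor prcomp rnorm rpois rnbinom rgamma
#'   runif rlnorm wilcox.test p.adjust phyper fisher.test qt qnorm pt hclust
#'   as.dist cutree dist predict setNames aggregate
#' @importFrom utils head write.table read.table
#' @importFrom methods as is
#' @importFrom mclust Mclust mclustBIC
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population z-score
#'
#' Standardizes a vector using the population (divide-by-n) standard
#' deviation, the convention used for all cross-cell-type and cross-region
#' scaling in this package.
#'
#' @param x Numeric vector.
#' @return Numeric vector with mean 0 and population sd 1 (all-`NA` if the
#'   input is constant).
#' @export
zscore_pop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mu) / s
}

#' Two-sided standard-normal critical value
#'
#' The cutoff used by the disproportionality gate: the (1 - alpha/2)
#' standard-normal quantile, 1.6449 at the default alpha = 0.10.
#'
#' @param alpha Two-sided significance level.
#' @return Positive critical value.
#' @export
z_critical <- function(alpha = 0.10) {
  stopifnot(alpha > 0, alpha < 1)
  qnorm(1 - alpha / 2)
}

#' Cell retention pass rate
#'
#' @param n_retained Number of cells retained after filtering.
#' @param n_input Number of cells before filtering.
#' @param digits Rounding applied to the percentage (default 1, the
#'   convention used when reporting run-level QC).
#' @return Percentage of cells retained.
#' @export
pass_rate <- function(n_retained, n_input, digits = 1) {
  stopifnot(n_input > 0, n_retained >= 0, n_retained <= n_input)
  round(100 * n_retained / n_input, digits)
}

## derive a stage-specific 32-bit seed from a root seed so stages are
## independently reproducible
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

## adjusted Rand index between two labelings (used for recovery checks)
#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
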