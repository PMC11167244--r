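#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate. Thin,
#' validated wrapper around [stats::p.adjust()] so that every stage of the
#' pipeline shares one FDR definition. Names (feature ids) are preserved in
#' their input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, optionally named.
#' @param ids Optional character vector of feature identifiers; defaults to
#'   `names(p)`.
#' @return Numeric vector of BH-adjusted values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.5))
#' @export
bh_adjust <- function(p, ids = names(p)) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (!is.null(ids) && length(ids) != length(p)) {
    stop("ids must match p in length")
  }
  adj <- stats::p.adjust(p, method = "BH")
  names(adj) <- ids
  adj
}

#' Partial Spearman correlation
#'
#' Rank correlation between `x` and `y` controlling for a single covariate
#' `z`, computed by applying the first-order partial-correlation identity
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}
#' to mid-ranked data. Used as the purity-adjusted co-expression statistic
#' (the RS score) throughout the pipeline.
#'
#' A constant `z` carries no information, so the function falls back to the
#' plain Spearman correlation of `x` and `y` (documented convention).
#'
#' @param x,y Numeric vectors of equal length (at least 4).
#' @param z Numeric covariate vector of the same length.
#' @return A single correlation in `[-1, 1]`.
#' @examples
#' partial_spearman(1:4, 1:4, c(1, 1, 2, 2))  # 1
#' @export
partial_spearman <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("missing values not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y: correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(z) == 0) {
    return(stats::cor(rx, ry))
  }
  rz <- rank(z)
  rxy <- stats::cor(rx, ry)
  rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den == 0) stop("control variable perfectly correlated with x or y")
  min(max((rxy - rxz * ryz) / den, -1), 1)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` counts annotated genes among `n` drawn without
#' replacement from a universe of `N` genes of which `K` are annotated. The
#' over-representation p-value used by [ora_enrichment()].
#'
#' @param k Observed overlap.
#' @param n Number of genes drawn (query size).
#' @param K Number of annotated genes in the universe.
#' @param N Universe size.
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeometric_tail(4, 4, 5, 10)  # 5/210
#' @export
hypergeometric_tail <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals))) {
    stop("k, n, K, N must be non-negative integers")
  }
  if (k > min(n, K) || n > N || K > N) {
    stop("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-group location test (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test used for differential expression. The
#' statistic is centred (`W - n_a n_b / 2`) so its sign indicates direction:
#' positive when `a` tends to exceed `b`. Exact p-values are used for small
#' tie-free samples (the [stats::wilcox.test()] default), otherwise the
#' normal approximation with continuity correction. When the centred
#' statistic is exactly zero (including fully tied data) the p-value is 1 by
#' convention.
#'
#' @param a,b Numeric vectors, each with at least 3 observations.
#' @return List with elements `statistic` and `p`.
#' @examples
#' two_group_test(c(10, 11, 12), c(1, 2, 3))
#' @export
two_group_test <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) stop("each group needs >= 3 values")
  if (anyNA(a) || anyNA(b)) stop("missing values not supported")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            correct = TRUE))
  stat <- unname(wt$statistic) - length(a) * length(b) / 2
  p <- if (stat == 0) 1 else min(wt$p.value, 1)
  list(statistic = stat, p = p)
}

#' Build a deterministic ranked gene list
#'
#' Sorts a named score vector in decreasing order, breaking score ties by
#' gene identifier (C-locale radix order) so every ranking in the pipeline is
#' reproducible.
#'
#' @param scores Named numeric vector (one score per gene, unique names).
#' @return The same vector sorted into rank order.
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || any(names(scores) == "")) {
    stop("scores must be fully named")
  }
  if (anyDuplicated(names(scores))) stop("duplicate gene ids in ranked list")
  if (anyNA(scores)) stop("missing scores not supported")
  scores[order(-scores, names(scores), method = "radix")]
}

# Vectorised Welch t-test over matrix rows; returns two-sided p-values.
# Rows with zero pooled variance get p = 1 when means agree, else p = 0.
welch_rows <- function(x1, x2) {
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  list(statistic = t, p = p, mean1 = m1, mean2 = m2)
}
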