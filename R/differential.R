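#' Tumor-vs-normal differential expression
#'
#' Per-feature Wilcoxon rank-sum test ([two_group_test()]) on log2-scale
#' expression, with the effect reported as `log2FC = mean(tumor) -
#' mean(normal)` and Benjamini-Hochberg adjustment across features. A
#' feature is called `up`/`down` when `fdr < fdr_threshold` and
#' `|log2FC| >= lfc_threshold`, otherwise `ns`.
#'
#' @param expr Numeric matrix, features in rows, samples in columns (log2
#'   scale).
#' @param labels Character vector (`"tumor"`/`"normal"`) aligned with the
#'   columns, or a data.frame with `sample` and `group` columns.
#' @param fdr_threshold,lfc_threshold Call thresholds (defaults 0.05 and 1).
#' @return `data.frame` ("DiffTable") with columns `id`, `log2fc`, `p`,
#'   `fdr`, `direction`.
#' @export
differential_expression <- function(expr, labels, fdr_threshold = 0.05,
                                    lfc_threshold = 1) {
  labels <- align_labels(labels, colnames(expr))
  is_t <- labels == "tumor"
  if (sum(is_t) < 3 || sum(!is_t) < 3) {
    stop("each group needs at least 3 samples")
  }
  tum <- expr[, is_t, drop = FALSE]
  nor <- expr[, !is_t, drop = FALSE]
  p <- numeric(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    p[i] <- two_group_test(tum[i, ], nor[i, ])$p
  }
  log2fc <- rowMeans(tum) - rowMeans(nor)
  fdr <- bh_adjust(p)
  direction <- ifelse(fdr < fdr_threshold & abs(log2fc) >= lfc_threshold,
                      ifelse(log2fc > 0, "up", "down"), "ns")
  data.frame(id = rownames(expr), log2fc = log2fc, p = p, fdr = fdr,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Tumor-vs-normal differential methylation per CpG site
#'
#' Tests each site on the M-value scale `M = log2((beta + eps) / (1 - beta +
#' eps))` (variance-stabilizing; the epsilon offset keeps boundary betas
#' finite) with a Welch t-test, while reporting the effect as the mean beta
#' difference `delta_beta = mean(tumor) - mean(normal)` on the original
#' scale. BH adjustment across sites; a site is differentially methylated
#' (`hyper`/`hypo`) iff `fdr < fdr_threshold` and `|delta_beta| >=
#' delta_threshold` (default 0, i.e. no minimum effect size).
#'
#' @param beta Numeric matrix of beta values in `[0, 1]`, sites in rows.
#' @param labels As in [differential_expression()].
#' @param fdr_threshold FDR call threshold (default 0.05).
#' @param delta_threshold Minimum `|delta_beta|` (default 0).
#' @param eps Offset in the M-value transform (default 0.01).
#' @return `data.frame` with columns `id`, `delta_beta`, `p`, `fdr`,
#'   `direction` (`hyper`/`hypo`/`ns`).
#' @export
differential_methylation <- function(beta, labels, fdr_threshold = 0.05,
                                     delta_threshold = 0, eps = 0.01) {
  if (anyNA(beta) || any(beta < 0 | beta > 1)) {
    stop("beta values must lie in [0, 1] with no missing values")
  }
  labels <- align_labels(labels, colnames(beta))
  is_t <- labels == "tumor"
  if (sum(is_t) < 3 || sum(!is_t) < 3) {
    stop("each group needs at least 3 samples")
  }
  M <- log2((beta + eps) / (1 - beta + eps))
  res <- welch_rows(M[, is_t, drop = FALSE], M[, !is_t, drop = FALSE])
  delta <- rowMeans(beta[, is_t, drop = FALSE]) -
    rowMeans(beta[, !is_t, drop = FALSE])
  fdr <- bh_adjust(res$p)
  direction <- ifelse(fdr < fdr_threshold & abs(delta) >= delta_threshold &
                        delta != 0,
                      ifelse(delta > 0, "hyper", "hypo"), "ns")
  data.frame(id = rownames(beta), delta_beta = delta, p = res$p, fdr = fdr,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Accepts either a label vector aligned to sample names or a two-column
# data.frame (sample, group); returns a "tumor"/"normal" vector in column
# order.
align_labels <- function(labels, sample_names) {
  if (is.data.frame(labels)) {
    if (!all(c("sample", "group") %in% names(labels))) {
      stop("label table needs 'sample' and 'group' columns")
    }
    idx <- match(sample_names, labels$sample)
    if (anyNA(idx)) stop("samples missing from label table")
    labels <- labels$group[idx]
  }
  labels <- as.character(labels)
  if (length(labels) != length(sample_names)) {
    stop("labels must match the number of samples")
  }
  if (!all(labels %in% c("tumor", "normal"))) {
    stop("labels must be 'tumor' or 'normal'")
  }
  if (!any(labels == "tumor") || !any(labels == "normal")) {
    stop("both groups must be present")
  }
  labels
}
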