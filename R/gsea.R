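#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running-sum statistic. Walking down the ranked list, the
#' running sum increases by `|score|^p` (normalised over in-set genes) at
#' each gene-set hit and decreases by `1/(N - N_hit)` at each miss; the
#' enrichment score (ES) is the signed maximum deviation from zero. When the
#' maximum positive and negative deviations tie in magnitude the positive
#' one is returned (deterministic convention).
#'
#' If every in-set gene has score exactly zero the hit increments fall back
#' to equal weights `1/N_hit` so the statistic stays defined.
#'
#' @param ranked Named numeric vector sorted in decreasing score order (see
#'   [ranked_list()]).
#' @param gene_set Character vector of gene ids; must intersect the list and
#'   must not cover it entirely.
#' @param p Weighting exponent (default 1, classic GSEA).
#' @param running If `TRUE`, also return the running-sum vector.
#' @return The ES (numeric scalar), or a list `(es, running_sum)` when
#'   `running = TRUE`.
#' @examples
#' r <- ranked_list(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1))
#' enrichment_score(r, "g1")  # 1
#' enrichment_score(r, "g4")  # -1
#' @export
enrichment_score <- function(ranked, gene_set, p = 1, running = FALSE) {
  N <- length(ranked)
  hits <- names(ranked) %in% gene_set
  k <- sum(hits)
  if (k == 0) stop("gene set does not intersect the ranked list")
  if (k == N) stop("gene set covers the whole ranked list: ES undefined")
  w <- abs(ranked)^p
  wh_total <- sum(w[hits])
  inc <- if (wh_total == 0) as.numeric(hits) / k else ifelse(hits, w, 0) / wh_total
  dev <- cumsum(inc - (!hits) / (N - k))
  es_pos <- max(dev)
  es_neg <- min(dev)
  # positive deviation wins magnitude ties (within numerical tolerance)
  es <- if (es_pos + es_neg >= -1e-9) es_pos else es_neg
  if (running) list(es = es, running_sum = dev) else es
}

# ES for a single hit-position set without materialising the running sum.
# w: |score|^p for the full ranked list; pos: sorted hit positions.
# The running sum attains its maximum immediately after a hit and its
# minimum immediately before one, so only 2k candidates are evaluated.
es_at_positions <- function(w, N, pos) {
  k <- length(pos)
  wh <- w[pos]
  NR <- sum(wh)
  cumhit <- if (NR == 0) seq_len(k) / k else cumsum(wh) / NR
  j <- seq_len(k)
  top <- cumhit - (pos - j) / (N - k)
  bottom <- c(0, cumhit[-k]) - (pos - j) / (N - k)
  es_pos <- max(top)
  es_neg <- min(bottom)
  if (es_pos + es_neg >= -1e-9) es_pos else es_neg
}

# Nominal p / NES from an observed ES and a vector of null ES values.
# Estimator: p = (1 + #{same-sign nulls at least as extreme}) /
# (1 + #same-sign nulls) — the add-one permutation estimator conditioned on
# the ES sign, which is uniform under the null and can never return zero.
# NES = ES / mean(|same-sign null ES|). With no same-sign nulls the p floor
# 1/(1 + n_null) is reported and NES is NA with a flag.
gsea_from_null <- function(es, null_es) {
  n_null <- length(null_es)
  if (es == 0) {
    return(list(nominal_p = 1, nes = 0, nes_defined = TRUE))
  }
  same <- null_es[sign(null_es) == sign(es)]
  if (length(same) == 0) {
    return(list(nominal_p = 1 / (1 + n_null), nes = NA_real_,
                nes_defined = FALSE))
  }
  n_ge <- sum(abs(same) >= abs(es))
  list(nominal_p = (1 + n_ge) / (1 + length(same)),
       nes = es / mean(abs(same)),
       nes_defined = TRUE)
}

#' GSEA significance by gene-label permutation
#'
#' Builds the permutation null for an enrichment score by reassigning gene-set
#' membership uniformly at random (set size preserved) and recomputing the ES.
#' The nominal p-value uses the add-one estimator conditioned on the sign of
#' the observed score,
#' `(1 + #{same-sign null ES with |ES| >= |observed|}) /
#' (1 + #same-sign null ES)`, which is uniform under the null and can never
#' return zero; the normalised enrichment score is
#' `NES = ES / mean(|same-sign null ES|)`.
#'
#' FDR q-values are computed across a batch of results by [gsea_fdr()]; the
#' returned object carries its null ES sample for that purpose.
#'
#' @param ranked Named numeric vector sorted decreasing ([ranked_list()]).
#' @param gene_set Character vector of member gene ids.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param p Weighting exponent.
#' @return Object of class `gsea_result`: list with `es`, `nes`, `nominal_p`,
#'   `fdr_q` (`NA` until [gsea_fdr()] is applied), `n_perm`, `seed`,
#'   `set_size`, `nes_defined`, and the `null_es` vector.
#' @export
gsea_significance <- function(ranked, gene_set, n_perm = 1000, seed, p = 1) {
  if (missing(seed)) stop("seed is required")
  if (n_perm < 100) stop("n_perm must be at least 100")
  es <- enrichment_score(ranked, gene_set, p = p)
  N <- length(ranked)
  k <- sum(names(ranked) %in% gene_set)
  w <- abs(ranked)^p
  set.seed(as.integer(seed))
  null_es <- vapply(seq_len(n_perm), function(i) {
    es_at_positions(w, N, sort.int(sample.int(N, k)))
  }, numeric(1))
  est <- gsea_from_null(es, null_es)
  structure(list(es = es, nes = est$nes, nominal_p = est$nominal_p,
                 fdr_q = NA_real_, n_perm = n_perm, seed = as.integer(seed),
                 set_size = k, nes_defined = est$nes_defined,
                 null_es = null_es),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA result: ES = %.4f, NES = %.4f, p = %.4g, q = %.4g (set size %d, %d permutations)\n",
              x$es, x$nes, x$nominal_p, x$fdr_q, x$set_size, x$n_perm))
  invisible(x)
}

#' FDR q-values for a batch of GSEA results
#'
#' Default method is the standard NES-pooled positive/negative procedure:
#' every null ES is normalised by its own list's mean same-sign null
#' magnitude, nulls are pooled across the batch, and for an observed
#' `NES* >= 0` the q-value is the ratio of the null tail fraction
#' `#{null NES >= NES*} / #{null NES >= 0}` to the observed tail fraction
#' `#{obs NES >= NES*} / #{obs NES >= 0}`, capped at 1 (mirrored for
#' negative scores). `method = "bh"` instead applies Benjamini-Hochberg to
#' the nominal p-values.
#'
#' @param results List of `gsea_result` objects from [gsea_significance()].
#' @param method `"nes_pooled"` (default) or `"bh"`.
#' @return The same list with `fdr_q` filled in on every element.
#' @export
gsea_fdr <- function(results, method = c("nes_pooled", "bh")) {
  method <- match.arg(method)
  if (length(results) == 0) return(results)
  if (method == "bh") {
    q <- bh_adjust(vapply(results, `[[`, numeric(1), "nominal_p"))
    for (i in seq_along(results)) results[[i]]$fdr_q <- q[[i]]
    return(results)
  }
  null_nes <- unlist(lapply(results, function(r) {
    pos <- r$null_es[r$null_es > 0]
    neg <- r$null_es[r$null_es < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) neg / mean(abs(neg)))
  }), use.names = FALSE)
  obs <- vapply(results, `[[`, numeric(1), "nes")
  n_null_pos <- sum(null_nes >= 0)
  n_null_neg <- sum(null_nes < 0)
  n_obs_pos <- sum(obs >= 0, na.rm = TRUE)
  n_obs_neg <- sum(obs < 0, na.rm = TRUE)
  for (i in seq_along(results)) {
    s <- obs[i]
    if (is.na(s)) {
      results[[i]]$fdr_q <- NA_real_
      next
    }
    if (s >= 0) {
      null_frac <- if (n_null_pos) sum(null_nes >= s) / n_null_pos else 0
      obs_tail <- sum(obs >= s, na.rm = TRUE) / n_obs_pos
    } else {
      null_frac <- if (n_null_neg) sum(null_nes <= s) / n_null_neg else 0
      obs_tail <- sum(obs <= s, na.rm = TRUE) / n_obs_neg
    }
    results[[i]]$fdr_q <- min(1, null_frac / obs_tail)
  }
  results
}

#' Rank genes by purity-adjusted co-expression with a lncRNA (RS score)
#'
#' The RS score of gene *g* for a candidate lncRNA is the partial Spearman
#' correlation between the lncRNA's expression and the gene's expression
#' across tumor samples, controlling for tumor purity. Marginal correlations
#' driven purely by tumor-cell fraction (a gene and a lncRNA both tracking
#' purity) are cancelled by the adjustment. Genes are returned sorted by
#' decreasing RS with ties broken by gene id.
#'
#' @param lnc_expr Numeric vector: the lncRNA's expression over tumor
#'   samples.
#' @param gene_expr Numeric matrix, genes in rows, tumor samples in columns
#'   (aligned with `lnc_expr`).
#' @param purity Numeric vector of tumor purities, aligned with samples.
#' @param adjust If `FALSE`, plain Spearman correlation is used (the
#'   uncorrected ranking, kept for the confounding sensitivity analysis).
#' @return Named numeric vector of RS scores in rank order (a ranked gene
#'   list for [enrichment_score()]).
#' @export
rs_rank_genes <- function(lnc_expr, gene_expr, purity, adjust = TRUE) {
  n <- length(lnc_expr)
  if (ncol(gene_expr) != n || length(purity) != n) {
    stop("samples misaligned between lnc_expr, gene_expr and purity")
  }
  if (n < 10) stop("need at least 10 tumor samples for RS ranking")
  if (stats::sd(lnc_expr) == 0) stop("constant lncRNA expression: no ranking possible")
  if (is.null(rownames(gene_expr))) stop("gene_expr must have rownames")
  rl <- rank(lnc_expr)
  rG <- t(apply(gene_expr, 1L, rank))
  r_xy <- as.vector(stats::cor(t(rG), rl))
  if (adjust && stats::sd(purity) > 0) {
    rp <- rank(purity)
    r_xz <- as.vector(stats::cor(t(rG), rp))
    r_yz <- stats::cor(rl, rp)
    den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
    rs <- (r_xy - r_xz * r_yz) / den
    rs[!is.finite(rs)] <- 0 # constant genes / purity-duplicate genes
    rs <- pmin(pmax(rs, -1), 1)
  } else {
    rs <- r_xy
    rs[!is.finite(rs)] <- 0
  }
  names(rs) <- rownames(gene_expr)
  ranked_list(rs)
}

#' Screen candidate lncRNAs for autophagy association (lncAut scoring)
#'
#' The three-step selection: (1) rank all genes by the purity-adjusted RS
#' score of each candidate lncRNA; (2) run permutation GSEA of the
#' differential autophagy gene set in that ranking; (3) convert the nominal
#' GSEA p-value to `lncAut = 1 - p` and select lncRNAs with
#' `lncAut > lncaut_threshold` and FDR q below `fdr_threshold`.
#'
#' @param candidates Character vector of candidate lncRNA ids (rows of
#'   `lnc_expr`).
#' @param lnc_expr lncRNA expression matrix (lncRNAs x tumor samples).
#' @param gene_expr Gene expression matrix (genes x tumor samples).
#' @param purity Tumor purity vector aligned with the tumor samples.
#' @param gene_set Character vector: the differential autophagy gene set.
#' @param n_perm Permutations per lncRNA.
#' @param seed Base seed; candidate *i* uses `seed + i`.
#' @param adjust Apply purity adjustment in the RS ranking.
#' @param lncaut_threshold Selection threshold on lncAut (strict `>`).
#' @param fdr_threshold Selection threshold on the GSEA FDR q.
#' @param fdr_method Passed to [gsea_fdr()].
#' @return `data.frame` with one row per candidate: `lncrna_id`, `es`,
#'   `nes`, `nominal_p`, `fdr_q`, `lncaut`, `selected`.
#' @export
lncaut_screen <- function(candidates, lnc_expr, gene_expr, purity,
                          gene_set, n_perm = 1000, seed, adjust = TRUE,
                          lncaut_threshold = 0.9, fdr_threshold = 0.05,
                          fdr_method = "nes_pooled") {
  if (missing(seed)) stop("seed is required")
  candidates <- sort(unique(candidates), method = "radix")
  missing_ids <- setdiff(candidates, rownames(lnc_expr))
  if (length(missing_ids)) {
    stop("candidates absent from lnc_expr: ", paste(missing_ids, collapse = ", "))
  }
  results <- vector("list", length(candidates))
  names(results) <- candidates
  for (i in seq_along(candidates)) {
    ranked <- rs_rank_genes(lnc_expr[candidates[i], ], gene_expr, purity,
                            adjust = adjust)
    results[[i]] <- gsea_significance(ranked, gene_set, n_perm = n_perm,
                                      seed = as.integer(seed) + i)
  }
  results <- gsea_fdr(results, method = fdr_method)
  lncaut_select(results, lncaut_threshold = lncaut_threshold,
                fdr_threshold = fdr_threshold)
}

#' Convert GSEA results to lncAut scores and apply the selection rule
#'
#' `lncaut = 1 - nominal_p`; a candidate is selected iff
#' `lncaut > lncaut_threshold` (strict) and `fdr_q < fdr_threshold`.
#'
#' @param results Named list of `gsea_result` objects (names = lncRNA ids)
#'   with `fdr_q` filled (see [gsea_fdr()]).
#' @param lncaut_threshold,fdr_threshold Selection thresholds.
#' @return `data.frame` with columns `lncrna_id`, `es`, `nes`, `nominal_p`,
#'   `fdr_q`, `lncaut`, `selected`.
#' @export
lncaut_select <- function(results, lncaut_threshold = 0.9,
                          fdr_threshold = 0.05) {
  if (length(results) == 0) {
    return(data.frame(lncrna_id = character(), es = numeric(),
                      nes = numeric(), nominal_p = numeric(),
                      fdr_q = numeric(), lncaut = numeric(),
                      selected = logical(), stringsAsFactors = FALSE))
  }
  if (is.null(names(results))) stop("results must be named by lncRNA id")
  out <- data.frame(
    lncrna_id = names(results),
    es = vapply(results, `[[`, numeric(1), "es"),
    nes = vapply(results, `[[`, numeric(1), "nes"),
    nominal_p = vapply(results, `[[`, numeric(1), "nominal_p"),
    fdr_q = vapply(results, `[[`, numeric(1), "fdr_q"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$lncaut <- 1 - out$nominal_p
  out$selected <- out$lncaut > lncaut_threshold &
    !is.na(out$fdr_q) & out$fdr_q < fdr_threshold
  out
}
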