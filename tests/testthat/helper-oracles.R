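# Independent brute-force oracles used across the test files. These are
# deliberately naive re-derivations (explicit loops, full enumeration) and
# never call the implementation paths they check.

# Running-sum GSEA enrichment score by explicit walk down the list.
es_oracle <- function(ranked, gene_set, p = 1) {
  N <- length(ranked)
  hits <- names(ranked) %in% gene_set
  k <- sum(hits)
  w <- abs(ranked)^p
  denom_hit <- sum(w[hits])
  run <- 0
  best_pos <- -Inf
  best_neg <- Inf
  for (i in seq_len(N)) {
    if (hits[i]) {
      run <- run + if (denom_hit == 0) 1 / k else w[i] / denom_hit
    } else {
      run <- run - 1 / (N - k)
    }
    best_pos <- max(best_pos, run)
    best_neg <- min(best_neg, run)
  }
  # same positive-wins tie rule as the implementation, with tolerance for
  # the different floating-point accumulation order
  if (best_pos + best_neg >= -1e-9) best_pos else best_neg
}

# P(X >= k) for the hypergeometric by enumerating all draws of size n.
hyper_oracle <- function(k, n, K, N) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(idx) sum(pop[idx]) >= k))
}

# Exact two-sided rank-sum p by enumerating all group assignments.
ranksum_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  W_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  W_null <- apply(idx, 2, function(i) sum(r[i]) - na * (na + 1) / 2)
  p <- 2 * min(mean(W_null <= W_obs), mean(W_null >= W_obs))
  min(p, 1)
}

# All-pairs interval containment check for site-to-region mapping.
overlap_oracle <- function(sites, regions) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(regions))) {
      if (sites$chrom[i] == regions$chrom[j] &&
          sites$position[i] >= regions$start[j] &&
          sites$position[i] < regions$end[j]) {
        rows[[length(rows) + 1]] <- data.frame(
          site_id = sites$site_id[i], lncrna_id = regions$name[j],
          role = regions$role[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(site_id = character(), lncrna_id = character(),
                      role = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$site_id, out$lncrna_id, out$role, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# Log-rank chi-square from per-event-time hypergeometric moments.
logrank_oracle <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Compact cohort used by unit tests (fast; acceptance tests use defaults).
small_config <- function(seed = 1,
                         n_targets_per_lnc = c(at_plus = 8, at_minus = 2),
                         ...) {
  cohort_config(n_tumor = 30, n_normal = 15, n_lncrna = 40, n_gene = 300,
                n_sites = 300, n_autophagy = 60,
                autophagy_split = c(at_plus = 28, at_minus = 16, both = 8,
                                    unknown = 8),
                n_planted_lnc = 4,
                n_targets_per_lnc = n_targets_per_lnc,
                n_drugs = 8, n_planted_drugs = 3, seed = seed, ...)
}

small_null_config <- function(seed = 1, ...) {
  small_config(seed = seed, delta_beta = 0, lnc_effect = 0, gene_effect = 0,
               coexpr_strength = 0, meth_expr_couple = 0, drug_effect = 0,
               hazard_log_hr = 0, ...)
}

random_ranked <- function(n, prefix = "g") {
  ranked_list(stats::setNames(stats::rnorm(n), sprintf("%s%03d", prefix,
                                                       seq_len(n))))
}
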