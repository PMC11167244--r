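#' Build the signed lncRNA-autophagy-gene regulatory network
#'
#' For every (selected lncRNA, autophagy gene) pair, computes the
#' purity-adjusted Spearman correlation (rho, the edge weight), a
#' t-approximation p-value (df = n - 3 with adjustment, n - 2 without), and
#' BH FDR across all tested pairs. An edge exists iff `|rho| >=
#' rho_threshold` and `fdr < fdr_threshold`; its sign is the sign of rho
#' (positive = the lncRNA up-regulates the gene).
#'
#' @param lnc_ids Character vector of selected lncRNA ids.
#' @param lnc_expr lncRNA expression matrix (lncRNAs x tumor samples).
#' @param autophagy_genes Character vector of (differential) autophagy gene
#'   ids, a subset of `rownames(gene_expr)`.
#' @param gene_expr Gene expression matrix (genes x tumor samples).
#' @param purity Tumor purity vector aligned with the samples.
#' @param rho_threshold,fdr_threshold Edge criteria (defaults 0.3, 0.05).
#' @param adjust Apply purity adjustment.
#' @return List with `edges` (rows satisfying the edge criterion) and
#'   `rho_table` (all tested pairs), both data.frames with columns
#'   `lncrna_id`, `gene_id`, `rho`, `p`, `fdr`, `sign`, `edge`.
#' @export
build_regulatory_network <- function(lnc_ids, lnc_expr, autophagy_genes,
                                     gene_expr, purity, rho_threshold = 0.3,
                                     fdr_threshold = 0.05, adjust = TRUE) {
  empty <- data.frame(lncrna_id = character(), gene_id = character(),
                      rho = numeric(), p = numeric(), fdr = numeric(),
                      sign = character(), edge = logical(),
                      stringsAsFactors = FALSE)
  if (length(lnc_ids) == 0) {
    warning("empty lncRNA set: returning an empty network")
    return(list(edges = empty, rho_table = empty))
  }
  lnc_ids <- sort(unique(lnc_ids), method = "radix")
  autophagy_genes <- sort(intersect(autophagy_genes, rownames(gene_expr)),
                          method = "radix")
  n <- ncol(gene_expr)
  sub <- gene_expr[autophagy_genes, , drop = FALSE]
  tabs <- lapply(lnc_ids, function(l) {
    rs <- rs_rank_genes(lnc_expr[l, ], sub, purity, adjust = adjust)
    rs <- rs[autophagy_genes] # undo rank ordering: fixed gene order
    data.frame(lncrna_id = l, gene_id = autophagy_genes, rho = unname(rs),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  df <- if (adjust && stats::sd(purity) > 0) n - 3 else n - 2
  r <- pmin(pmax(tab$rho, -0.999999), 0.999999)
  tstat <- r * sqrt(df / (1 - r^2))
  tab$p <- 2 * stats::pt(-abs(tstat), df)
  tab$fdr <- bh_adjust(tab$p)
  tab$sign <- ifelse(tab$rho > 0, "positive", "negative")
  tab$edge <- abs(tab$rho) >= rho_threshold & tab$fdr < fdr_threshold
  list(edges = tab[tab$edge, , drop = FALSE], rho_table = tab)
}

#' Classify a lncRNA as autophagy-promoting or autophagy-inhibiting
#'
#' One-sample Wilcoxon signed-rank tests of the lncRNA's correlations with
#' annotated genes against zero, separately over AT+ (autophagy-promoting)
#' and AT- (autophagy-inhibiting) genes. The lncRNA is inferred
#' autophagy-promoting when the AT+ correlations are significantly positive
#' and the AT- correlations significantly negative (both at `alpha`);
#' autophagy-inhibiting in the mirrored case; otherwise unclassified.
#'
#' @param lncrna_id The lncRNA to classify.
#' @param rho_table `rho_table` from [build_regulatory_network()].
#' @param annotation `data.frame` with columns `gene_id` and `group`
#'   (`"AT+"`, `"AT-"`, `"both"`, `"unknown"`).
#' @param alpha Significance level for each one-sided test.
#' @return List with `p_plus`, `p_minus` (two-sided signed-rank p-values),
#'   `median_plus`, `median_minus`, `inferred_role` (`"promoting"`,
#'   `"inhibiting"` or `"unclassified"`), and `reason`.
#' @export
activator_inhibitor_test <- function(lncrna_id, rho_table, annotation,
                                     alpha = 0.05) {
  tab <- rho_table[rho_table$lncrna_id == lncrna_id, , drop = FALSE]
  plus_genes <- annotation$gene_id[annotation$group == "AT+"]
  minus_genes <- annotation$gene_id[annotation$group == "AT-"]
  rho_plus <- tab$rho[tab$gene_id %in% plus_genes]
  rho_minus <- tab$rho[tab$gene_id %in% minus_genes]
  if (length(rho_plus) < 3 || length(rho_minus) < 3) {
    return(list(p_plus = NA_real_, p_minus = NA_real_,
                median_plus = NA_real_, median_minus = NA_real_,
                inferred_role = "unclassified",
                reason = "fewer than 3 annotated AT+ or AT- correlations"))
  }
  wp <- suppressWarnings(stats::wilcox.test(rho_plus, mu = 0))
  wm <- suppressWarnings(stats::wilcox.test(rho_minus, mu = 0))
  med_p <- stats::median(rho_plus)
  med_m <- stats::median(rho_minus)
  role <- if (wp$p.value < alpha && wm$p.value < alpha &&
              med_p > 0 && med_m < 0) {
    "promoting"
  } else if (wp$p.value < alpha && wm$p.value < alpha &&
             med_p < 0 && med_m > 0) {
    "inhibiting"
  } else {
    "unclassified"
  }
  list(p_plus = wp$p.value, p_minus = wm$p.value, median_plus = med_p,
       median_minus = med_m, inferred_role = role, reason = NA_character_)
}

#' Extract a lncRNA's target gene set from the network
#'
#' The lncRNA's edge partners, both signs, as a character vector (the
#' "potential target genes" used by the drug screen).
#'
#' @param lncrna_id The lncRNA.
#' @param edges Edge table from [build_regulatory_network()].
#' @return Sorted character vector of gene ids (possibly empty, with a
#'   warning).
#' @export
target_gene_set <- function(lncrna_id, edges) {
  genes <- sort(unique(edges$gene_id[edges$lncrna_id == lncrna_id]),
                method = "radix")
  if (length(genes) == 0) {
    warning("lncRNA ", lncrna_id, " has no edges: empty target set")
  }
  genes
}

#' Drug-lncRNA screen by enrichment of target sets in drug signatures
#'
#' For each (drug, lncRNA) combination, runs permutation GSEA (the same
#' kernel as the lncAut stage) of the lncRNA's target gene set against the
#' drug's ranked perturbation signature. FDR q-values are pooled across all
#' tested pairs (NES-normalised positive/negative procedure); a pair is
#' reported when `fdr_q < fdr_threshold`, with direction `induces` (NES >
#' 0, the drug up-regulates the targets) or `represses` (NES < 0).
#'
#' Target genes absent from a signature are dropped for that pair; a
#' warning is issued when coverage falls below `min_coverage`.
#'
#' @param target_sets Named list (by lncRNA id) of character gene vectors.
#' @param signatures Named list (by drug id) of ranked named score vectors
#'   (see [generate_drug_signatures()] or [ranked_list()]).
#' @param n_perm Permutations per pair.
#' @param seed Base seed; pair *i* (row-major over drugs x lncRNAs) uses
#'   `seed + i`.
#' @param fdr_threshold Reporting threshold (default 0.01).
#' @param min_coverage Minimum fraction of the target set that must be
#'   present in a signature before a coverage warning fires.
#' @return `data.frame` with one row per tested pair: `drug_id`,
#'   `lncrna_id`, `es`, `nes`, `nominal_p`, `fdr_q`, `direction`,
#'   `reported`.
#' @export
drug_lncrna_screen <- function(target_sets, signatures, n_perm = 1000, seed,
                               fdr_threshold = 0.01, min_coverage = 0.5) {
  if (missing(seed)) stop("seed is required")
  target_sets <- target_sets[vapply(target_sets, length, integer(1)) > 0]
  empty <- data.frame(drug_id = character(), lncrna_id = character(),
                      es = numeric(), nes = numeric(), nominal_p = numeric(),
                      fdr_q = numeric(), direction = character(),
                      reported = logical(), stringsAsFactors = FALSE)
  if (length(target_sets) == 0 || length(signatures) == 0) {
    warning("nothing to screen: empty target sets or signatures")
    return(empty)
  }
  drugs <- sort(names(signatures), method = "radix")
  lncs <- sort(names(target_sets), method = "radix")
  results <- list()
  meta <- list()
  i <- 0L
  for (d in drugs) {
    sig <- signatures[[d]]
    for (l in lncs) {
      i <- i + 1L
      targets <- intersect(target_sets[[l]], names(sig))
      if (length(targets) < min_coverage * length(target_sets[[l]])) {
        warning(sprintf("pair (%s, %s): only %d/%d target genes covered",
                        d, l, length(targets), length(target_sets[[l]])))
      }
      if (length(targets) == 0 || length(targets) == length(sig)) next
      results[[length(results) + 1L]] <-
        gsea_significance(sig, targets, n_perm = n_perm,
                          seed = as.integer(seed) + i)
      meta[[length(meta) + 1L]] <- c(drug_id = d, lncrna_id = l)
    }
  }
  if (length(results) == 0) return(empty)
  results <- gsea_fdr(results, method = "nes_pooled")
  out <- do.call(rbind, lapply(seq_along(results), function(j) {
    r <- results[[j]]
    data.frame(drug_id = meta[[j]][["drug_id"]],
               lncrna_id = meta[[j]][["lncrna_id"]],
               es = r$es, nes = r$nes, nominal_p = r$nominal_p,
               fdr_q = r$fdr_q, stringsAsFactors = FALSE)
  }))
  out$direction <- ifelse(!is.na(out$nes) & out$nes > 0, "induces", "represses")
  out$reported <- !is.na(out$fdr_q) & out$fdr_q < fdr_threshold
  out
}

#' Over-representation analysis against named function sets
#'
#' Hypergeometric upper-tail test ([hypergeometric_tail()]) of a query gene
#' set against each function set, with BH adjustment across sets. Function
#' sets are intersected with the universe; a set disjoint from the universe
#' is skipped with a warning.
#'
#' @param genes Character vector of query genes; must be a subset of
#'   `universe`.
#' @param function_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector, the gene universe.
#' @return `data.frame` with columns `set`, `k` (overlap), `n` (query
#'   size), `K` (set size in universe), `N` (universe size), `p`, `fdr`.
#' @export
ora_enrichment <- function(genes, function_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  if (!all(genes %in% universe)) stop("query genes must lie in the universe")
  genes <- unique(genes)
  keep <- vapply(function_sets,
                 function(s) length(intersect(s, universe)) > 0, logical(1))
  if (any(!keep)) {
    warning("skipping sets disjoint from the universe: ",
            paste(names(function_sets)[!keep], collapse = ", "))
  }
  function_sets <- function_sets[keep]
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(function_sets), function(nm) {
    s <- intersect(function_sets[[nm]], universe)
    k <- length(intersect(genes, s))
    data.frame(set = nm, k = k, n = n, K = length(s), N = N,
               p = hypergeometric_tail(k, n, length(s), N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  }
  out$fdr <- bh_adjust(out$p)
  out
}
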