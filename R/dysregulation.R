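#' Map CpG sites into lncRNA promoter/enhancer regions
#'
#' Interval overlap of point CpG coordinates against 0-based half-open
#' regions: site `s` maps to region `r` iff `r.start <= s.position <
#' r.end` on the same chromosome. A site may map to several regions.
#' Implemented with [GenomicRanges::findOverlaps()].
#'
#' @param sites `data.frame` with columns `site_id`, `chrom`, `position`
#'   (0-based).
#' @param regions `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), `name` (lncRNA id), `strand`, `role`
#'   (`promoter`/`enhancer`). Strand is carried but ignored in the overlap
#'   (array-level CpG methylation is strand-symmetric).
#' @return `data.frame` with one row per (site, region) overlap: `site_id`,
#'   `lncrna_id`, `role`.
#' @export
map_sites_to_regions <- function(sites, regions) {
  need_s <- c("site_id", "chrom", "position")
  need_r <- c("chrom", "start", "end", "name", "role")
  if (!all(need_s %in% names(sites))) stop("sites needs columns: site_id, chrom, position")
  if (!all(need_r %in% names(regions))) stop("regions needs columns: chrom, start, end, name, role")
  if (nrow(sites) == 0 || nrow(regions) == 0) {
    return(data.frame(site_id = character(), lncrna_id = character(),
                      role = character(), stringsAsFactors = FALSE))
  }
  if (any(regions$start >= regions$end)) stop("regions must satisfy start < end")
  chroms <- union(sites$chrom, regions$chrom)  # shared seqlevel universe
  gr_sites <- GenomicRanges::GRanges(
    factor(sites$chrom, levels = chroms),
    IRanges::IRanges(start = sites$position + 1L, width = 1L))
  gr_regions <- GenomicRanges::GRanges(
    factor(regions$chrom, levels = chroms),
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_regions)
  out <- data.frame(
    site_id = sites$site_id[S4Vectors::queryHits(ov)],
    lncrna_id = regions$name[S4Vectors::subjectHits(ov)],
    role = regions$role[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)
  out[order(out$site_id, out$lncrna_id, out$role, method = "radix"), ,
      drop = FALSE]
}

#' Call DNA methylation-dysregulated lncRNAs
#'
#' A lncRNA (per region role) is dysregulated iff all four clauses hold:
#' (i) it is differentially expressed; (ii) at least one differentially
#' methylated site lies in the region; (iii) the site's methylation
#' direction is opposite to the expression direction (hyper + down or
#' hypo + up); (iv) the Spearman correlation between the site's beta values
#' and the lncRNA's expression across shared tumor samples is negative with
#' BH FDR < `corr_fdr` (BH taken across all tested site-lncRNA pairs).
#' Each region is summarized by its most significant (minimum DM FDR)
#' passing site. Clauses (iii) and (iv) can be relaxed individually for
#' sensitivity analyses.
#'
#' @param de_lnc DiffTable from [differential_expression()] on lncRNAs.
#' @param dm DiffTable from [differential_methylation()].
#' @param mapping Output of [map_sites_to_regions()].
#' @param beta Methylation matrix (sites x samples).
#' @param lnc_expr lncRNA expression matrix (lncRNAs x samples).
#' @param tumor_samples Character vector of tumor sample ids present in
#'   both matrices (correlation is computed on tumor samples only).
#' @param corr_fdr FDR threshold for the anti-correlation clause.
#' @param require_direction,require_correlation Toggle clauses (iii)/(iv).
#' @return `data.frame` with one row per tested lncRNA x role: `lncrna_id`,
#'   `role`, `expr_direction`, `meth_direction`, `n_dm_sites`, `best_site`,
#'   `rho`, `corr_p`, `corr_fdr`, `dysregulated`.
#' @export
call_dysregulated_lncrnas <- function(de_lnc, dm, mapping, beta, lnc_expr,
                                      tumor_samples, corr_fdr = 0.05,
                                      require_direction = TRUE,
                                      require_correlation = TRUE) {
  tumor_samples <- intersect(tumor_samples,
                             intersect(colnames(beta), colnames(lnc_expr)))
  if (length(tumor_samples) < 4) {
    stop("no (or too few) shared tumor samples between beta and expression")
  }
  de_called <- de_lnc[de_lnc$direction %in% c("up", "down"), , drop = FALSE]
  dm_called <- dm[dm$direction %in% c("hyper", "hypo"), , drop = FALSE]
  cand <- merge(mapping, dm_called, by.x = "site_id", by.y = "id")
  cand <- merge(cand, de_called[, c("id", "direction")],
                by.x = "lncrna_id", by.y = "id",
                suffixes = c("_meth", "_expr"))
  empty <- data.frame(lncrna_id = character(), role = character(),
                      expr_direction = character(),
                      meth_direction = character(), n_dm_sites = integer(),
                      best_site = character(), rho = numeric(),
                      corr_p = numeric(), corr_fdr = numeric(),
                      dysregulated = logical(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0) return(empty)
  opposite <- (cand$direction_meth == "hyper" & cand$direction_expr == "down") |
    (cand$direction_meth == "hypo" & cand$direction_expr == "up")
  if (require_direction) cand <- cand[opposite, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  # anti-correlation clause across tumor samples, BH over tested pairs
  cand$rho <- NA_real_
  cand$corr_p <- NA_real_
  for (i in seq_len(nrow(cand))) {
    b <- beta[cand$site_id[i], tumor_samples]
    e <- lnc_expr[cand$lncrna_id[i], tumor_samples]
    if (stats::sd(b) == 0 || stats::sd(e) == 0) {
      cand$rho[i] <- 0
      cand$corr_p[i] <- 1
    } else {
      ct <- suppressWarnings(stats::cor.test(b, e, method = "spearman",
                                             exact = FALSE))
      cand$rho[i] <- unname(ct$estimate)
      cand$corr_p[i] <- ct$p.value
    }
  }
  cand$corr_fdr_val <- bh_adjust(cand$corr_p)
  cand$pass <- if (require_correlation) {
    cand$rho < 0 & cand$corr_fdr_val < corr_fdr
  } else {
    rep(TRUE, nrow(cand))
  }

  # summarize per lncRNA x role by the most significant passing site
  # (falling back to the most significant tested site when none pass)
  key <- paste(cand$lncrna_id, cand$role, sep = "\r")
  rows <- lapply(split(seq_len(nrow(cand)), key), function(idx) {
    sub <- cand[idx, , drop = FALSE]
    sub <- sub[order(sub$fdr, sub$site_id, method = "radix"), , drop = FALSE]
    best <- if (any(sub$pass)) sub[sub$pass, , drop = FALSE][1, ] else sub[1, ]
    data.frame(lncrna_id = best$lncrna_id, role = best$role,
               expr_direction = best$direction_expr,
               meth_direction = best$direction_meth,
               n_dm_sites = nrow(sub), best_site = best$site_id,
               rho = best$rho, corr_p = best$corr_p,
               corr_fdr = best$corr_fdr_val,
               dysregulated = any(sub$pass), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$lncrna_id, out$role, method = "radix"), , drop = FALSE]
}
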