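#' Configuration for the synthetic tumor/normal cohort
#'
#' Collects every knob of the planted-effect simulator into one validated
#' object. Defaults describe the cohort used throughout the package's own
#' calibration: 60 tumors vs 30 normals, 120 lncRNAs of which 8 carry
#' planted promoter/enhancer methylation dysregulation, 1000 genes of which
#' 150 are autophagy-annotated, 2000 CpG sites, and 20 drug signatures of
#' which 5 carry a planted target-set shift.
#'
#' Planted lncRNAs alternate direction: odd-indexed ones are
#' hypermethylated + down-regulated, even-indexed ones
#' hypomethylated + up-regulated. Tumor purity acts as a
#' latent factor loading on a subset of genes and non-planted lncRNAs so
#' that unadjusted co-expression rankings are confounded.
#'
#' @param n_tumor,n_normal Sample counts per group.
#' @param n_lncrna,n_gene,n_sites Feature counts (lncRNAs, genes, CpGs).
#' @param n_autophagy Number of autophagy-annotated genes.
#' @param autophagy_split Named counts of AT+ (promoting), AT- (inhibiting),
#'   both, unknown annotations; must sum to `n_autophagy`.
#' @param n_planted_lnc Number of planted dysregulated autophagy lncRNAs.
#' @param n_targets_per_lnc Named counts of AT+ and AT- target genes driven
#'   by each planted lncRNA.
#' @param delta_beta Planted tumor-minus-normal mean beta difference, in
#'   `[0, 1)` (0 disables the methylation effect).
#' @param lnc_effect Planted lncRNA expression shift (log2 units).
#' @param gene_effect Differential-expression shift (log2 units) applied to
#'   autophagy genes and a background set of genes.
#' @param coexpr_strength Target |Spearman correlation| between a planted
#'   lncRNA and its target genes after purity adjustment, in `[0, 1)`.
#' @param meth_expr_couple Loading of the shared latent that anti-correlates
#'   a planted lncRNA's expression with its region methylation.
#' @param purity_frac_autophagy,purity_frac_background,purity_frac_lnc
#'   Fractions of autophagy genes, background genes and non-planted lncRNAs
#'   loading on the purity factor.
#' @param purity_loading Loading magnitude of the purity factor.
#' @param n_drugs,n_planted_drugs Drug signature counts.
#' @param drug_effect Score shift applied to a planted drug's target genes.
#' @param hazard_log_hr Planted log hazard ratio per SD of the prognostic
#'   lncRNA's expression.
#' @param censor_horizon Administrative censoring time (days).
#' @param noise_sd Residual SD of expression values (log2 units).
#' @param sites_promoter,sites_enhancer CpG sites simulated per promoter and
#'   per enhancer.
#' @param seed Integer seed; fully determines the cohort.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_tumor = 60, n_normal = 30, n_lncrna = 120,
                          n_gene = 1000, n_sites = 2000, n_autophagy = 150,
                          autophagy_split = c(at_plus = 70, at_minus = 40,
                                              both = 20, unknown = 20),
                          n_planted_lnc = 8,
                          n_targets_per_lnc = c(at_plus = 20, at_minus = 5),
                          delta_beta = 0.3, lnc_effect = 2, gene_effect = 1.5,
                          coexpr_strength = 0.6, meth_expr_couple = 0.8,
                          purity_frac_autophagy = 0.3,
                          purity_frac_background = 0.1,
                          purity_frac_lnc = 0.3, purity_loading = 1,
                          n_drugs = 20, n_planted_drugs = 5,
                          drug_effect = 1.5,
                          hazard_log_hr = 0.7, censor_horizon = 1825,
                          noise_sd = 1, sites_promoter = 1,
                          sites_enhancer = 2, seed = 1) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_lncrna = n_lncrna,
              n_gene = n_gene, n_sites = n_sites, n_autophagy = n_autophagy,
              autophagy_split = autophagy_split,
              n_planted_lnc = n_planted_lnc,
              n_targets_per_lnc = n_targets_per_lnc,
              delta_beta = delta_beta, lnc_effect = lnc_effect,
              gene_effect = gene_effect, coexpr_strength = coexpr_strength,
              meth_expr_couple = meth_expr_couple,
              purity_frac_autophagy = purity_frac_autophagy,
              purity_frac_background = purity_frac_background,
              purity_frac_lnc = purity_frac_lnc,
              purity_loading = purity_loading, n_drugs = n_drugs,
              n_planted_drugs = n_planted_drugs, drug_effect = drug_effect,
              hazard_log_hr = hazard_log_hr,
              censor_horizon = censor_horizon, noise_sd = noise_sd,
              sites_promoter = sites_promoter,
              sites_enhancer = sites_enhancer, seed = as.integer(seed))
  counts <- c(n_tumor, n_normal, n_lncrna, n_gene, n_sites, n_autophagy,
              n_drugs)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (n_planted_lnc < 0 || n_planted_drugs < 0) stop("planted counts must be >= 0")
  if (n_planted_lnc > n_lncrna) stop("n_planted_lnc exceeds n_lncrna")
  if (n_planted_drugs > n_drugs) stop("n_planted_drugs exceeds n_drugs")
  if (sum(autophagy_split) != n_autophagy) {
    stop("autophagy_split must sum to n_autophagy")
  }
  if (!all(c("at_plus", "at_minus", "both", "unknown") %in%
           names(autophagy_split))) {
    stop("autophagy_split needs names at_plus, at_minus, both, unknown")
  }
  if (delta_beta < 0 || delta_beta >= 1) stop("delta_beta must lie in [0, 1)")
  if (coexpr_strength < 0 || coexpr_strength >= 1) {
    stop("coexpr_strength must lie in [0, 1)")
  }
  if (any(n_targets_per_lnc > autophagy_split[c("at_plus", "at_minus")])) {
    stop("n_targets_per_lnc exceeds available AT+/AT- genes")
  }
  if (censor_horizon <= 0) stop("censor_horizon must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(cfg, class = "cohort_config")
}

#' Null configuration: all planted effects zero
#'
#' Same cohort dimensions as [cohort_config()] but every planted effect
#' (methylation difference, expression shifts, co-expression, drug shift,
#' hazard) set to zero, for false-positive calibration of the pipeline.
#' The purity confounder is retained: it is a property of the cohort, not a
#' planted signal.
#'
#' @param seed Integer seed.
#' @param ... Further overrides passed to [cohort_config()].
#' @return Object of class `cohort_config`.
#' @export
null_config <- function(seed = 1, ...) {
  cohort_config(delta_beta = 0, lnc_effect = 0, gene_effect = 0,
                coexpr_strength = 0, meth_expr_couple = 0, drug_effect = 0,
                hazard_log_hr = 0, seed = seed, ...)
}

pad_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Generate a synthetic tumor/normal multi-omics cohort with planted effects
#'
#' Simulates, from a single seed, every input the pipeline consumes:
#' log2-scale lncRNA and gene expression, a CpG beta matrix with promoter and
#' enhancer regions per lncRNA, tumor purity, autophagy annotations, and the
#' planted-truth labels used to score recovery.
#'
#' Construction, in brief:
#' * Beta values are generated on the logit scale and inverse-transformed,
#'   giving `[0, 1]` support with realistic heteroscedasticity. Planted
#'   sites have group means `(1 -/+ delta_beta)/2` vs `(1 +/- delta_beta)/2`
#'   so the tumor-normal mean beta difference equals `delta_beta`.
#' * Each planted lncRNA shares a per-sample latent with its region's CpGs
#'   (coefficient `meth_expr_couple`, opposite signs), making methylation
#'   and expression negatively correlated by construction, and shifts
#'   expression by `lnc_effect` opposite to its methylation change.
#' * Each planted lncRNA drives its AT+ targets positively and AT- targets
#'   negatively with partial correlation magnitude about `coexpr_strength`.
#' * A purity factor (scores = scaled tumor purity; normals receive scores
#'   from the same distribution so no spurious tumor-vs-normal difference
#'   arises) loads on fractions of autophagy genes, background genes and
#'   non-planted lncRNAs, confounding unadjusted co-expression.
#'
#' @param config A [cohort_config()] object.
#' @return List with elements `lnc_expr`, `gene_expr` (features x samples),
#'   `beta` (sites x samples), `purity` (named, tumor samples), `labels`
#'   (data.frame sample/group), `sites` (site_id/chrom/position), `regions`
#'   (BED-style promoter/enhancer table), `autophagy` (gene_id/group),
#'   `gene_sets` (named list incl. the autophagy set), and `truth`
#'   (planted-truth labels; see Details).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_t <- config$n_tumor
  n_n <- config$n_normal
  n_s <- n_t + n_n
  samples <- c(sprintf("T%03d", seq_len(n_t)), sprintf("N%03d", seq_len(n_n)))
  tumor <- samples[seq_len(n_t)]
  labels <- data.frame(sample = samples,
                       group = rep(c("tumor", "normal"), c(n_t, n_n)),
                       stringsAsFactors = FALSE)
  lnc_ids <- pad_ids("LNC", config$n_lncrna)
  gene_ids <- pad_ids("G", config$n_gene)
  site_ids <- sprintf("cg%05d", seq_len(config$n_sites))

  # purity + latent factor scores (normals drawn from the same law so the
  # factor cannot masquerade as a tumor-vs-normal difference)
  purity_raw <- stats::runif(n_s, 0.5, 0.95)
  purity <- stats::setNames(purity_raw[seq_len(n_t)], tumor)
  fscore <- as.vector(scale(purity_raw))

  # autophagy annotation and DE gene assignment
  autophagy_genes <- sort(sample(gene_ids, config$n_autophagy), method = "radix")
  split <- config$autophagy_split
  grp <- sample(rep(c("AT+", "AT-", "both", "unknown"),
                    times = split[c("at_plus", "at_minus", "both", "unknown")]))
  autophagy <- data.frame(gene_id = autophagy_genes, group = grp,
                          stringsAsFactors = FALSE)
  background <- setdiff(gene_ids, autophagy_genes)
  de_background <- sample(background, min(150, length(background)))
  de_genes <- c(autophagy_genes, de_background)
  de_sign <- stats::setNames(sample(c(-1, 1), length(de_genes), replace = TRUE),
                             de_genes)

  # purity-factor loadings (stratified: autophagy vs background vs lncRNA)
  conf_auto <- sample(autophagy_genes,
                      round(config$purity_frac_autophagy * length(autophagy_genes)))
  conf_bg <- sample(background,
                    round(config$purity_frac_background * length(background)))
  conf_genes <- c(conf_auto, conf_bg)

  # planted lncRNAs: alternate hyper+down / hypo+up
  planted_lnc <- sort(sample(lnc_ids, config$n_planted_lnc), method = "radix")
  direction <- stats::setNames(
    rep(c("hyper_down", "hypo_up"), length.out = config$n_planted_lnc),
    planted_lnc)
  conf_lnc <- sample(setdiff(lnc_ids, planted_lnc),
                     round(config$purity_frac_lnc *
                             (config$n_lncrna - config$n_planted_lnc)))

  # gene expression
  gene_expr <- matrix(stats::rnorm(config$n_gene * n_s, sd = config$noise_sd),
                      nrow = config$n_gene, dimnames = list(gene_ids, samples))
  gene_expr <- gene_expr + stats::rnorm(config$n_gene, mean = 8, sd = 1)
  gene_expr[de_genes, seq_len(n_t)] <-
    gene_expr[de_genes, seq_len(n_t)] + de_sign * config$gene_effect
  gene_expr[conf_genes, ] <- gene_expr[conf_genes, ] +
    config$purity_loading * rep(fscore, each = length(conf_genes))

  # lncRNA expression
  lnc_expr <- matrix(stats::rnorm(config$n_lncrna * n_s, sd = config$noise_sd),
                     nrow = config$n_lncrna, dimnames = list(lnc_ids, samples))
  lnc_expr <- lnc_expr + stats::rnorm(config$n_lncrna, mean = 6, sd = 1)
  lnc_expr[conf_lnc, ] <- lnc_expr[conf_lnc, ] +
    config$purity_loading * rep(fscore, each = length(conf_lnc))
  meth_latent <- matrix(stats::rnorm(config$n_planted_lnc * n_t),
                        nrow = max(config$n_planted_lnc, 1),
                        dimnames = if (config$n_planted_lnc)
                          list(planted_lnc, tumor))
  for (l in planted_lnc) {
    shift <- if (direction[[l]] == "hyper_down") -config$lnc_effect else config$lnc_effect
    lnc_expr[l, seq_len(n_t)] <- lnc_expr[l, seq_len(n_t)] + shift +
      config$meth_expr_couple * meth_latent[l, ]
  }

  # planted lncRNA -> autophagy target coupling (on realized tumor expression)
  at_plus_genes <- autophagy$gene_id[autophagy$group == "AT+"]
  at_minus_genes <- autophagy$gene_id[autophagy$group == "AT-"]
  cstr <- config$coexpr_strength
  bcoef <- if (cstr > 0) config$noise_sd * cstr / sqrt(1 - cstr^2) else 0
  target_sets <- stats::setNames(vector("list", config$n_planted_lnc), planted_lnc)
  # deal targets from the least-used genes first (random tie-break) so no
  # gene accumulates many couplings and per-edge correlations stay near
  # coexpr_strength
  use_plus <- stats::setNames(integer(length(at_plus_genes)), at_plus_genes)
  use_minus <- stats::setNames(integer(length(at_minus_genes)), at_minus_genes)
  deal <- function(use, k) {
    ord <- order(use, stats::runif(length(use)))
    names(use)[ord[seq_len(k)]]
  }
  for (l in planted_lnc) {
    tp <- deal(use_plus, config$n_targets_per_lnc[["at_plus"]])
    tm <- deal(use_minus, config$n_targets_per_lnc[["at_minus"]])
    use_plus[tp] <- use_plus[tp] + 1L
    use_minus[tm] <- use_minus[tm] + 1L
    target_sets[[l]] <- data.frame(
      gene_id = c(tp, tm),
      sign = rep(c(1, -1), c(length(tp), length(tm))),
      stringsAsFactors = FALSE)
    if (bcoef > 0) {
      z <- as.vector(scale(lnc_expr[l, seq_len(n_t)]))
      gene_expr[c(tp, tm), seq_len(n_t)] <-
        gene_expr[c(tp, tm), seq_len(n_t)] +
        bcoef * outer(target_sets[[l]]$sign, z)
    }
  }

  # genomic layout: one promoter + one enhancer per lncRNA on chr1;
  # background CpGs live on chr2 and map to nothing
  tss <- 10000L + (seq_len(config$n_lncrna) - 1L) * 10000L
  regions <- rbind(
    data.frame(chrom = "chr1", start = tss - 2000L, end = tss + 500L,
               name = lnc_ids, score = 0L, strand = "+", role = "promoter",
               stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", start = tss + 3000L, end = tss + 4000L,
               name = lnc_ids, score = 0L, strand = "+", role = "enhancer",
               stringsAsFactors = FALSE))
  prom_pos <- lapply(seq_len(config$n_lncrna), function(i) {
    tss[i] - 2000L + as.integer(round(seq(200, 2300,
                                          length.out = config$sites_promoter)))
  })
  enh_pos <- lapply(seq_len(config$n_lncrna), function(i) {
    tss[i] + 3000L + as.integer(round(seq(200, 800,
                                          length.out = config$sites_enhancer)))
  })
  region_site_pos <- c(unlist(prom_pos), unlist(enh_pos))
  region_site_lnc <- c(rep(lnc_ids, each = config$sites_promoter),
                       rep(lnc_ids, each = config$sites_enhancer))
  n_region_sites <- length(region_site_pos)
  if (n_region_sites > config$n_sites) {
    stop("n_sites too small for the requested per-region site density")
  }
  n_bg_sites <- config$n_sites - n_region_sites
  sites <- data.frame(
    site_id = site_ids,
    chrom = rep(c("chr1", "chr2"), c(n_region_sites, n_bg_sites)),
    position = c(region_site_pos,
                 sort(sample.int(10000000L, n_bg_sites))),
    stringsAsFactors = FALSE)
  site_lnc <- stats::setNames(rep(NA_character_, config$n_sites), site_ids)
  site_lnc[seq_len(n_region_sites)] <- region_site_lnc

  # methylation: logit-scale generation, planted group means symmetric
  # around 0.5 so the realized mean beta difference equals delta_beta
  base_p <- stats::runif(config$n_sites, 0.1, 0.9)
  logit_mu <- matrix(stats::qlogis(base_p), nrow = config$n_sites,
                     ncol = n_s, dimnames = list(site_ids, samples))
  planted_sites <- character(0)
  for (l in planted_lnc) {
    idx <- which(site_lnc == l)
    planted_sites <- c(planted_sites, site_ids[idx])
    hyper <- direction[[l]] == "hyper_down"
    p_tum <- if (hyper) (1 + config$delta_beta) / 2 else (1 - config$delta_beta) / 2
    p_nor <- 1 - p_tum
    logit_mu[idx, seq_len(n_t)] <- stats::qlogis(p_tum)
    logit_mu[idx, n_t + seq_len(n_n)] <- stats::qlogis(p_nor)
    logit_mu[idx, seq_len(n_t)] <- logit_mu[idx, seq_len(n_t)] -
      config$meth_expr_couple *
      rep(meth_latent[l, ], each = length(idx))
  }
  beta <- stats::plogis(logit_mu +
                          matrix(stats::rnorm(config$n_sites * n_s, sd = 0.3),
                                 nrow = config$n_sites))
  beta <- pmin(pmax(beta, 0), 1)

  # planted drug pairs: first n_planted_drugs drugs, planted lncRNAs used
  # cyclically, expected NES sign alternating + / -
  drug_ids <- sprintf("DRUG%02d", seq_len(config$n_drugs))
  drug_pairs <- if (config$n_planted_drugs > 0 && config$n_planted_lnc > 0) {
    data.frame(
      drug_id = drug_ids[seq_len(config$n_planted_drugs)],
      lncrna_id = rep(planted_lnc, length.out = config$n_planted_drugs),
      sign = rep(c(1, -1), length.out = config$n_planted_drugs),
      stringsAsFactors = FALSE)
  } else {
    data.frame(drug_id = character(), lncrna_id = character(),
               sign = numeric(), stringsAsFactors = FALSE)
  }

  prognostic <- if (config$n_planted_lnc > 0) {
    up <- planted_lnc[direction == "hypo_up"]
    if (length(up)) up[1] else planted_lnc[1]
  } else NA_character_

  truth <- list(
    dysregulated_lnc_ids = planted_lnc,
    direction = direction,
    autophagy_lnc_ids = planted_lnc,
    confounded_lnc_ids = sort(conf_lnc, method = "radix"),
    target_sets = target_sets,
    planted_site_ids = planted_sites,
    drug_pairs = drug_pairs,
    prognostic_lnc_id = prognostic,
    true_log_hr = config$hazard_log_hr)

  list(lnc_expr = lnc_expr, gene_expr = gene_expr, beta = beta,
       purity = purity, labels = labels, sites = sites, regions = regions,
       autophagy = autophagy,
       gene_sets = list(autophagy = autophagy$gene_id),
       truth = truth, config = config)
}

#' Generate per-drug perturbation signatures with planted target shifts
#'
#' Each drug's signature is a ranked gene list (decreasing differential
#' expression statistic under perturbation). Non-planted drugs score every
#' gene `N(0, 1)`; for a planted `(drug, lncRNA, sign)` pair the lncRNA's
#' target genes are shifted by `sign * drug_effect`, pushing them toward the
#' top (`sign > 0`, drug induces the targets) or bottom (`sign < 0`).
#'
#' @param config A [cohort_config()].
#' @param truth The `truth` element of [generate_cohort()] output.
#' @param target_sets Named list (by lncRNA) of data.frames with a `gene_id`
#'   column; defaults to `truth$target_sets`.
#' @param gene_ids Character vector, the gene universe.
#' @return Named list of ranked named score vectors, one per drug.
#' @export
generate_drug_signatures <- function(config, truth,
                                     target_sets = truth$target_sets,
                                     gene_ids) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  pairs <- truth$drug_pairs
  if (nrow(pairs)) {
    for (l in unique(pairs$lncrna_id)) {
      ts <- target_sets[[l]]
      if (is.null(ts) || nrow(ts) == 0) {
        stop("empty target set for planted lncRNA ", l)
      }
    }
  }
  drug_ids <- sprintf("DRUG%02d", seq_len(config$n_drugs))
  sigs <- stats::setNames(vector("list", config$n_drugs), drug_ids)
  for (d in drug_ids) {
    score <- stats::setNames(stats::rnorm(length(gene_ids)), gene_ids)
    hit <- pairs[pairs$drug_id == d, , drop = FALSE]
    if (nrow(hit) == 1 && config$drug_effect > 0) {
      tg <- target_sets[[hit$lncrna_id]]$gene_id
      score[tg] <- score[tg] + hit$sign * config$drug_effect
    }
    sigs[[d]] <- ranked_list(score)
  }
  sigs
}

#' Generate survival outcomes driven by the planted prognostic lncRNA
#'
#' Event times are exponential with per-sample log hazard
#' `true_log_hr * z + 0.3 * I(sex = male) - 0.3 * I(race = groupB)` where
#' `z` is the standardized expression of the prognostic lncRNA; the two
#' categorical covariates stand in for clinical parameters and are
#' independent of expression. Administrative censoring at
#' `config$censor_horizon`.
#'
#' @param config A [cohort_config()].
#' @param truth The `truth` element of [generate_cohort()] output.
#' @param lnc_expr lncRNA expression matrix restricted to the samples to
#'   simulate (typically tumor samples).
#' @return `data.frame` with columns `sample`, `time`, `event`, `sex`,
#'   `race`.
#' @export
generate_survival <- function(config, truth, lnc_expr) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$censor_horizon <= 0) stop("censoring horizon must be positive")
  lnc <- truth$prognostic_lnc_id
  if (is.na(lnc) || !(lnc %in% rownames(lnc_expr))) {
    stop("prognostic lncRNA absent from lnc_expr")
  }
  set.seed(config$seed + 2L)
  n <- ncol(lnc_expr)
  z <- as.vector(scale(lnc_expr[lnc, ]))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  race <- sample(c("groupA", "groupB"), n, replace = TRUE)
  lp <- truth$true_log_hr * z + 0.3 * (sex == "male") - 0.3 * (race == "groupB")
  base_rate <- 1 / (0.5 * config$censor_horizon)
  raw <- stats::rexp(n, rate = base_rate * exp(lp))
  time <- pmin(raw, config$censor_horizon)
  data.frame(sample = colnames(lnc_expr), time = time,
             event = as.integer(raw < config$censor_horizon),
             sex = sex, race = race, stringsAsFactors = FALSE)
}
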