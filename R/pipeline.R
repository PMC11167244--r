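#' Pipeline thresholds and settings
#'
#' All tunable thresholds of the end-to-end analysis, with the defaults
#' used throughout: expression calls at FDR < 0.05 and |log2FC| >= 1,
#' methylation calls at FDR < 0.05, anti-correlation clause at FDR < 0.05,
#' lncAut selection at lncAut > 0.9 and FDR < 0.05, network edges at
#' |rho| >= 0.3 and FDR < 0.05, drug pairs at FDR < 0.01, survival screen
#' at alpha = 0.05.
#'
#' @param de_fdr,de_lfc Differential-expression call thresholds.
#' @param dm_fdr Differential-methylation FDR threshold.
#' @param corr_fdr Methylation-expression anti-correlation FDR threshold.
#' @param lncaut_threshold,lncaut_fdr lncAut selection thresholds.
#' @param edge_rho,edge_fdr Network edge criteria.
#' @param drug_fdr Drug-pair reporting threshold.
#' @param survival_alpha Prognostic screen significance level.
#' @param n_perm Permutations per GSEA.
#' @param purity_adjust Apply purity adjustment in RS rankings.
#' @param seed Global seed; stages derive sub-seeds by fixed offsets
#'   (lncAut stage: seed + 10000; drug stage: seed + 20000).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(de_fdr = 0.05, de_lfc = 1, dm_fdr = 0.05,
                            corr_fdr = 0.05, lncaut_threshold = 0.9,
                            lncaut_fdr = 0.05, edge_rho = 0.3,
                            edge_fdr = 0.05, drug_fdr = 0.01,
                            survival_alpha = 0.05, n_perm = 1000,
                            purity_adjust = TRUE, seed = 1) {
  cfg <- list(de_fdr = de_fdr, de_lfc = de_lfc, dm_fdr = dm_fdr,
              corr_fdr = corr_fdr, lncaut_threshold = lncaut_threshold,
              lncaut_fdr = lncaut_fdr, edge_rho = edge_rho,
              edge_fdr = edge_fdr, drug_fdr = drug_fdr,
              survival_alpha = survival_alpha, n_perm = n_perm,
              purity_adjust = isTRUE(purity_adjust), seed = as.integer(seed))
  probs <- c(de_fdr, dm_fdr, corr_fdr, lncaut_fdr, edge_fdr, drug_fdr,
             survival_alpha)
  if (any(probs < 0 | probs > 1)) stop("FDR/alpha thresholds must lie in [0, 1]")
  if (lncaut_threshold < 0 || lncaut_threshold > 1) {
    stop("lncaut_threshold must lie in [0, 1]")
  }
  if (edge_rho < 0 || edge_rho > 1) stop("edge_rho must lie in [0, 1]")
  if (n_perm < 100) stop("n_perm must be at least 100")
  structure(cfg, class = "pipeline_config")
}

#' Run the full dysregulated-autophagy-lncRNA pipeline on a cohort directory
#'
#' Executes the stages in order — differential expression (lncRNAs, genes),
#' differential methylation, dysregulation calling, lncAut GSEA selection,
#' signed regulatory network, drug screen, prognostic screen — reading the
#' standard-format inputs written by [simulate_cohort_files()] (or
#' equivalent real data) from `input_dir` and writing one TSV per stage plus
#' a JSON run report to `output_dir`. Stage outputs are pure functions of
#' the inputs and `config`; rerunning with identical inputs reproduces the
#' stage TSVs byte for byte (the report additionally carries wall-clock
#' timings).
#'
#' An empty selection at any stage short-circuits: later stages write empty
#' tables and the report notes where the cascade stopped.
#'
#' @param input_dir Directory with `lnc_expr.tsv`, `gene_expr.tsv`,
#'   `beta.tsv`, `labels.tsv`, `purity.tsv`, `sites.tsv`, `regions.bed`,
#'   `autophagy.gmt`, `autophagy_annotation.tsv`, `drug_signatures.tsv`,
#'   `survival.tsv`.
#' @param output_dir Directory for stage outputs (created if needed).
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage banners on stderr.
#' @return Invisibly, the run report (also serialized to `report.json`):
#'   per-stage counts, the config echo, and timings.
#' @export
run_pipeline <- function(input_dir, output_dir, config = pipeline_config(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  lnc_expr <- read_matrix_tsv(file.path(input_dir, "lnc_expr.tsv"))
  gene_expr <- read_matrix_tsv(file.path(input_dir, "gene_expr.tsv"))
  beta <- read_matrix_tsv(file.path(input_dir, "beta.tsv"))
  labels <- as.data.frame(data.table::fread(file.path(input_dir, "labels.tsv")))
  purity_tab <- as.data.frame(data.table::fread(file.path(input_dir, "purity.tsv")))
  purity <- stats::setNames(purity_tab$purity, purity_tab$sample)
  sites <- as.data.frame(data.table::fread(file.path(input_dir, "sites.tsv")))
  regions <- read_bed(file.path(input_dir, "regions.bed"))
  gene_sets <- read_gmt(file.path(input_dir, "autophagy.gmt"))
  annotation <- as.data.frame(data.table::fread(
    file.path(input_dir, "autophagy_annotation.tsv")))
  signatures <- read_drug_signatures(file.path(input_dir, "drug_signatures.tsv"))
  surv <- as.data.frame(data.table::fread(file.path(input_dir, "survival.tsv")))
  tumor_samples <- labels$sample[labels$group == "tumor"]
  purity <- purity[tumor_samples]
  if (anyNA(purity)) stop("purity missing for some tumor samples")

  # stage 1: differential expression + methylation
  say("[1/7] differential expression")
  de_lnc <- clock("de", {
    differential_expression(lnc_expr, labels, config$de_fdr, config$de_lfc)
  })
  de_gene <- differential_expression(gene_expr, labels, config$de_fdr,
                                     config$de_lfc)
  data.table::fwrite(de_lnc, file.path(output_dir, "de_lncrna.tsv"), sep = "\t")
  data.table::fwrite(de_gene, file.path(output_dir, "de_gene.tsv"), sep = "\t")

  say("[2/7] differential methylation")
  dm <- clock("dm", differential_methylation(beta, labels, config$dm_fdr))
  data.table::fwrite(dm, file.path(output_dir, "dm_sites.tsv"), sep = "\t")

  # stage 2: dysregulation calling
  say("[3/7] dysregulation calling")
  mapping <- map_sites_to_regions(sites, regions)
  calls <- clock("dysregulation", {
    call_dysregulated_lncrnas(de_lnc, dm, mapping, beta, lnc_expr,
                              tumor_samples, corr_fdr = config$corr_fdr)
  })
  data.table::fwrite(calls, file.path(output_dir, "dysregulation.tsv"), sep = "\t")
  dysregulated <- sort(unique(calls$lncrna_id[calls$dysregulated]),
                       method = "radix")

  # stage 3: lncAut GSEA selection over the differential autophagy set
  say("[4/7] lncAut GSEA selection (%d candidates)", length(dysregulated))
  diff_autophagy <- intersect(gene_sets$autophagy,
                              de_gene$id[de_gene$direction != "ns"])
  lt <- lnc_expr[, tumor_samples, drop = FALSE]
  gt <- gene_expr[, tumor_samples, drop = FALSE]
  lncaut <- clock("lncaut", {
    if (length(dysregulated) && length(diff_autophagy)) {
      lncaut_screen(dysregulated, lt, gt, purity, diff_autophagy,
                    n_perm = config$n_perm, seed = config$seed + 10000L,
                    adjust = config$purity_adjust,
                    lncaut_threshold = config$lncaut_threshold,
                    fdr_threshold = config$lncaut_fdr)
    } else {
      lncaut_select(list())
    }
  })
  data.table::fwrite(lncaut, file.path(output_dir, "lncaut.tsv"), sep = "\t")
  selected <- lncaut$lncrna_id[lncaut$selected]

  # stage 4: signed regulatory network
  say("[5/7] regulatory network (%d selected lncRNAs)", length(selected))
  net <- clock("network", {
    if (length(selected) && length(diff_autophagy)) {
      suppressWarnings(build_regulatory_network(
        selected, lt, diff_autophagy, gt, purity,
        rho_threshold = config$edge_rho, fdr_threshold = config$edge_fdr,
        adjust = config$purity_adjust))
    } else {
      suppressWarnings(build_regulatory_network(character(0), lt,
                                                diff_autophagy, gt, purity))
    }
  })
  data.table::fwrite(net$edges, file.path(output_dir, "network_edges.tsv"),
                     sep = "\t")
  roles <- do.call(rbind, lapply(selected, function(l) {
    r <- activator_inhibitor_test(l, net$rho_table, annotation)
    data.frame(lncrna_id = l, p_plus = r$p_plus, p_minus = r$p_minus,
               inferred_role = r$inferred_role, stringsAsFactors = FALSE)
  }))
  if (is.null(roles)) {
    roles <- data.frame(lncrna_id = character(), p_plus = numeric(),
                        p_minus = numeric(), inferred_role = character(),
                        stringsAsFactors = FALSE)
  }
  data.table::fwrite(roles, file.path(output_dir, "lncrna_roles.tsv"), sep = "\t")

  # stage 5: drug screen
  say("[6/7] drug-lncRNA screen")
  target_sets <- stats::setNames(
    lapply(selected, function(l) suppressWarnings(target_gene_set(l, net$edges))),
    selected)
  pairs <- clock("drugs", {
    if (length(target_sets)) {
      suppressWarnings(drug_lncrna_screen(
        target_sets, signatures, n_perm = config$n_perm,
        seed = config$seed + 20000L, fdr_threshold = config$drug_fdr))
    } else {
      suppressWarnings(drug_lncrna_screen(list(), signatures,
                                          seed = config$seed + 20000L))
    }
  })
  data.table::fwrite(pairs, file.path(output_dir, "drug_pairs.tsv"), sep = "\t")

  # stage 6: prognostic screen
  say("[7/7] prognostic screen")
  covariates <- setdiff(names(surv), c("sample", "time", "event"))
  prognostic <- clock("survival", {
    if (length(selected)) {
      suppressWarnings(prognostic_screen(selected, lnc_expr, surv,
                                         covariates = covariates,
                                         alpha = config$survival_alpha))
    } else {
      data.frame(lncrna_id = character(), logrank_chi2 = numeric(),
                 logrank_p = numeric(), cox_beta = numeric(),
                 cox_hr = numeric(), cox_p = numeric(),
                 km_significant = logical(), independent = logical(),
                 stringsAsFactors = FALSE)
    }
  })
  data.table::fwrite(prognostic, file.path(output_dir, "prognostic.tsv"),
                     sep = "\t")

  report <- list(
    counts = list(
      de_lncrna = sum(de_lnc$direction != "ns"),
      de_gene = sum(de_gene$direction != "ns"),
      dm_sites = sum(dm$direction != "ns"),
      diff_autophagy_genes = length(diff_autophagy),
      dysregulated_lncrna = length(dysregulated),
      dysregulated_promoter = sum(calls$dysregulated & calls$role == "promoter"),
      dysregulated_enhancer = sum(calls$dysregulated & calls$role == "enhancer"),
      selected_autophagy_lncrna = length(selected),
      network_edges = nrow(net$edges),
      network_genes = length(unique(net$edges$gene_id)),
      drug_pairs_reported = sum(pairs$reported),
      drug_pairs_positive = sum(pairs$reported & pairs$nes > 0),
      drug_pairs_negative = sum(pairs$reported & pairs$nes < 0),
      km_significant = sum(prognostic$km_significant),
      independent_prognostic = sum(prognostic$independent)),
    short_circuit = if (length(dysregulated) == 0) {
      "dysregulation"
    } else if (length(selected) == 0) "lncaut" else NA,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("autolnc")),
    timings_sec = timings)
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
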