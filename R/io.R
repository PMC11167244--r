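#' Read / write a feature-by-sample matrix as TSV
#'
#' Features in rows (first column = feature id), samples in columns with a
#' header row of sample ids. Duplicate feature ids and non-numeric cells are
#' rejected with located errors.
#'
#' @param path File path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("matrix TSV needs an id column plus data columns: ", path)
  ids <- dt[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate feature id '", ids[duplicated(ids)][1], "' in ", path)
  }
  vals <- as.data.frame(dt[, -1, drop = FALSE])
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                   bad, names(vals)[j], path))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' @rdname read_matrix_tsv
#' @param m Numeric matrix with rownames and colnames.
#' @param id_col Name for the id column in the header.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  out <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Lines with fewer than three fields are rejected with the line number.
#'
#' @param path File path.
#' @return Named list of character vectors (descriptions in the
#'   `"description"` attribute).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    sets <- list()
    attr(sets, "description") <- character(0)
    return(sets)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short)) {
    stop("GMT parse error at line ", short[1],
         ": fewer than 3 tab-separated fields in ", path)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Character vector of per-set descriptions (recycled).
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  if (length(sets) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write lncRNA regions as BED (plus a role column)
#'
#' Six standard BED columns (0-based half-open; `name` = lncRNA id, score
#' unused, strand carried) plus a seventh `role` column restricted to
#' `promoter`/`enhancer`. Malformed lines are rejected with their line
#' number.
#'
#' @param path File path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `role`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 7) {
      stop("BED parse error at line ", i, ": expected 7 fields, got ",
           length(f), " in ", path)
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop("BED parse error at line ", i, ": non-integer coordinates in ", path)
    }
    if (start >= end) {
      stop("BED parse error at line ", i, ": start >= end in ", path)
    }
    if (!f[7] %in% c("promoter", "enhancer")) {
      stop("BED parse error at line ", i,
           ": role must be 'promoter' or 'enhancer' in ", path)
    }
  }
  out <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.integer(vapply(fields, `[`, character(1), 2)),
    end = as.integer(vapply(fields, `[`, character(1), 3)),
    name = vapply(fields, `[`, character(1), 4),
    score = vapply(fields, `[`, character(1), 5),
    strand = vapply(fields, `[`, character(1), 6),
    role = vapply(fields, `[`, character(1), 7),
    stringsAsFactors = FALSE)
  out
}

#' @rdname read_bed
#' @param regions `data.frame` as returned by [read_bed()].
#' @export
write_bed <- function(regions, path) {
  need <- c("chrom", "start", "end", "name", "score", "strand", "role")
  if (!all(need %in% names(regions))) {
    stop("regions needs columns: ", paste(need, collapse = ", "))
  }
  data.table::fwrite(regions[, need], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a generated cohort to a directory of standard-format files
#'
#' Serializes everything [generate_cohort()], [generate_drug_signatures()]
#' and [generate_survival()] produce: expression and methylation matrices
#' as TSV, regions as 7-column BED, the autophagy gene set as GMT, the
#' annotation / purity / labels / sites / survival tables as TSV, drug
#' signatures as one combined long TSV (`drug_id`, `gene_id`, `score`), and
#' the planted truth as a TSV sidecar.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the generated cohort list (with `signatures` and
#'   `survival` attached).
#' @export
simulate_cohort_files <- function(config, dir) {
  cohort <- generate_cohort(config)
  sigs <- generate_drug_signatures(config, cohort$truth,
                                   gene_ids = rownames(cohort$gene_expr))
  surv <- generate_survival(config, cohort$truth,
                            cohort$lnc_expr[, cohort$labels$sample[
                              cohort$labels$group == "tumor"], drop = FALSE])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$lnc_expr, file.path(dir, "lnc_expr.tsv"), "lncrna_id")
  write_matrix_tsv(cohort$gene_expr, file.path(dir, "gene_expr.tsv"), "gene_id")
  write_matrix_tsv(cohort$beta, file.path(dir, "beta.tsv"), "site_id")
  data.table::fwrite(cohort$labels, file.path(dir, "labels.tsv"), sep = "\t")
  data.table::fwrite(data.frame(sample = names(cohort$purity),
                                purity = unname(cohort$purity)),
                     file.path(dir, "purity.tsv"), sep = "\t")
  data.table::fwrite(cohort$sites, file.path(dir, "sites.tsv"), sep = "\t")
  write_bed(cohort$regions, file.path(dir, "regions.bed"))
  write_gmt(cohort$gene_sets, file.path(dir, "autophagy.gmt"),
            descriptions = "autophagy gene set")
  data.table::fwrite(cohort$autophagy, file.path(dir, "autophagy_annotation.tsv"),
                     sep = "\t")
  sig_long <- do.call(rbind, lapply(names(sigs), function(d) {
    data.frame(drug_id = d, gene_id = names(sigs[[d]]),
               score = unname(sigs[[d]]), stringsAsFactors = FALSE)
  }))
  data.table::fwrite(sig_long, file.path(dir, "drug_signatures.tsv"), sep = "\t")
  data.table::fwrite(surv, file.path(dir, "survival.tsv"), sep = "\t")
  truth_tab <- data.frame(
    lncrna_id = cohort$truth$dysregulated_lnc_ids,
    direction = unname(cohort$truth$direction),
    prognostic = cohort$truth$dysregulated_lnc_ids ==
      cohort$truth$prognostic_lnc_id,
    stringsAsFactors = FALSE)
  data.table::fwrite(truth_tab, file.path(dir, "truth.tsv"), sep = "\t")
  cohort$signatures <- sigs
  cohort$survival <- surv
  invisible(cohort)
}

#' Read drug signatures from the combined long TSV
#'
#' @param path TSV with columns `drug_id`, `gene_id`, `score`.
#' @return Named list of ranked named score vectors.
#' @export
read_drug_signatures <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("drug_id", "gene_id", "score")
  if (!all(need %in% names(dt))) {
    stop("drug signature TSV needs columns: ", paste(need, collapse = ", "))
  }
  split_idx <- split(seq_len(nrow(dt)), dt$drug_id)
  lapply(split_idx, function(idx) {
    ranked_list(stats::setNames(dt$score[idx], dt$gene_id[idx]))
  })
}
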