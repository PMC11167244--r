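#' Kaplan-Meier curves and log-rank test between two groups
#'
#' Product-limit survival estimates per group and the 1-df log-rank
#' chi-square built from per-event-time hypergeometric moments, via
#' [survival::survfit()] and [survival::survdiff()].
#'
#' @param records `data.frame` with columns `time` (> 0) and `event`
#'   (0/1).
#' @param group Factor/character vector with exactly two levels, aligned
#'   with the rows of `records`.
#' @return List with `fit` (the `survfit` object), `chi2` and `p`.
#' @export
km_logrank <- function(records, group) {
  validate_survival(records)
  group <- as.factor(group)
  if (length(group) != nrow(records)) stop("group must match records")
  if (nlevels(droplevels(group)) != 2) stop("exactly two non-empty groups required")
  ev <- tapply(records$event, group, sum)
  if (any(ev == 0)) stop("each group needs at least one event")
  s <- survival::Surv(records$time, records$event)
  fit <- survival::survfit(s ~ group)
  sd <- survival::survdiff(s ~ group)
  chi2 <- unname(sd$chisq)
  list(fit = fit, chi2 = chi2, p = stats::pchisq(chi2, df = 1,
                                                 lower.tail = FALSE))
}

#' Multivariate Cox proportional hazards fit
#'
#' Maximizes the Breslow partial likelihood via [survival::coxph()] and
#' returns per-covariate estimates with Wald confidence intervals from the
#' observed information. Categorical covariates are dummy-coded with the
#' first level as reference. Suspected monotone-likelihood separation
#' (|beta| > 10 or SE > 100) and non-convergence are flagged.
#'
#' @param records `data.frame` with columns `time`, `event`.
#' @param covariates `data.frame` of covariates aligned with `records`
#'   (numeric or categorical).
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `cox_result`: list with `table` (data.frame:
#'   `term`, `beta`, `hr`, `ci_lower`, `ci_upper`, `se`, `p`), `n`,
#'   `n_events`, `converged`, `separation`.
#' @export
cox_fit <- function(records, covariates, ties = c("breslow", "efron"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  validate_survival(records)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(records)) {
    stop("covariates must match records in rows")
  }
  constant <- vapply(covariates, function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    stop("constant covariate(s): ", paste(names(covariates)[constant],
                                          collapse = ", "))
  }
  if (sum(records$event) < 2) stop("too few events for a Cox fit")
  dat <- cbind(records[, c("time", "event")], covariates)
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = dat,
                         ties = ties)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  separation <- any(abs(beta) > 10 | se > 100, na.rm = TRUE)
  converged <- !anyNA(beta) && fit$iter < 20 && !separation
  tab <- data.frame(term = names(beta), beta = unname(beta),
                    hr = exp(unname(beta)),
                    ci_lower = exp(unname(beta) - zq * se),
                    ci_upper = exp(unname(beta) + zq * se),
                    se = unname(se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (separation) {
    warning("possible monotone likelihood (separation): estimates unreliable")
  }
  structure(list(table = tab, n = nrow(dat),
                 n_events = sum(records$event), converged = converged,
                 separation = separation, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d, converged = %s\n",
              x$n, x$n_events, x$converged))
  print(x$table, digits = 3)
  invisible(x)
}

#' Prognostic screen of candidate lncRNAs
#'
#' Stage 1: split tumor samples at the median expression of each lncRNA
#' (high = expression strictly above the median) and keep lncRNAs with
#' log-rank p < `alpha`. Stage 2: for each survivor, fit a multivariate Cox
#' model with the standardized (continuous) lncRNA expression plus the
#' clinical covariates; the lncRNA is an independent prognostic factor iff
#' its Cox term has p < `alpha`.
#'
#' @param lnc_ids Candidate lncRNA ids (rows of `lnc_expr`).
#' @param lnc_expr lncRNA expression matrix (lncRNAs x samples).
#' @param records Survival `data.frame` with `sample`, `time`, `event` and
#'   covariate columns.
#' @param covariates Character vector of covariate column names in
#'   `records` (default `c("sex", "race")`).
#' @param alpha Significance threshold for both stages.
#' @param split_quantile Quantile for the KM grouping (default 0.5 =
#'   median).
#' @return `data.frame`: `lncrna_id`, `logrank_chi2`, `logrank_p`,
#'   `cox_beta`, `cox_hr`, `cox_p`, `km_significant`, `independent`.
#' @export
prognostic_screen <- function(lnc_ids, lnc_expr, records,
                              covariates = c("sex", "race"), alpha = 0.05,
                              split_quantile = 0.5) {
  validate_survival(records)
  if (!all(covariates %in% names(records))) {
    stop("covariates missing from records: ",
         paste(setdiff(covariates, names(records)), collapse = ", "))
  }
  shared <- intersect(records$sample, colnames(lnc_expr))
  if (length(shared) < 10) stop("too few samples shared between expression and survival")
  rec <- records[match(shared, records$sample), , drop = FALSE]
  rows <- lapply(sort(lnc_ids, method = "radix"), function(l) {
    out <- data.frame(lncrna_id = l, logrank_chi2 = NA_real_,
                      logrank_p = NA_real_, cox_beta = NA_real_,
                      cox_hr = NA_real_, cox_p = NA_real_,
                      km_significant = FALSE, independent = FALSE,
                      stringsAsFactors = FALSE)
    e <- lnc_expr[l, shared]
    cut <- stats::quantile(e, split_quantile, names = FALSE)
    grp <- ifelse(e > cut, "high", "low")
    if (length(unique(grp)) < 2) {
      warning("lncRNA ", l, ": degenerate expression split, skipped")
      return(out)
    }
    km <- tryCatch(km_logrank(rec, grp), error = function(err) NULL)
    if (is.null(km)) return(out)
    out$logrank_chi2 <- km$chi2
    out$logrank_p <- km$p
    out$km_significant <- km$p < alpha
    if (!out$km_significant) return(out)
    covs <- rec[, covariates, drop = FALSE]
    covs$lnc <- as.vector(scale(e))
    cx <- cox_fit(rec, covs)
    row <- cx$table[cx$table$term == "lnc", , drop = FALSE]
    if (nrow(row) == 1 && cx$converged) {
      out$cox_beta <- row$beta
      out$cox_hr <- row$hr
      out$cox_p <- row$p
      out$independent <- row$p < alpha
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(lncrna_id = character(), logrank_chi2 = numeric(),
                      logrank_p = numeric(), cox_beta = numeric(),
                      cox_hr = numeric(), cox_p = numeric(),
                      km_significant = logical(), independent = logical(),
                      stringsAsFactors = FALSE)
  }
  out
}

validate_survival <- function(records) {
  if (!is.data.frame(records) || !all(c("time", "event") %in% names(records))) {
    stop("records needs 'time' and 'event' columns")
  }
  if (any(records$time <= 0)) stop("times must be positive")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(records)
}
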