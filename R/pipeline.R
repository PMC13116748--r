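# End-to-end analysis: scoring -> baseline associations -> ROC/Youden ->
# logistic models, assembled into a single report object.

#' Analysis configuration
#'
#' @param tipi_cutoff fallback TIPI cut-off used only when an analysis is
#'   run with `fixed_cutoff = TRUE`; 11.41 is the published cohort-specific
#'   value and is deliberately not applied by default, since the cut-off is
#'   a data-derived quantity.
#' @param sii_unit_scale multiplicative scale for the SII when blood counts
#'   are recorded on a scale other than 1e9/L.
#' @param roc_candidate_rule candidate-threshold rule for ROC/Youden:
#'   `"midpoint"` or `"observed"`.
#' @param fisher_threshold expected-count threshold routing 2 x 2 tables to
#'   Fisher's exact test (default 5).
#' @param logistic_max_iter,logistic_tol IRLS controls for [fit_logistic()].
#' @param level confidence level for intervals.
#' @return List of class `tipi_config`.
#' @export
tipi_config <- function(tipi_cutoff = 11.41, sii_unit_scale = 1,
                        roc_candidate_rule = c("midpoint", "observed"),
                        fisher_threshold = 5, logistic_max_iter = 100,
                        logistic_tol = 1e-10, level = 0.95) {
  structure(list(tipi_cutoff = tipi_cutoff, sii_unit_scale = sii_unit_scale,
                 roc_candidate_rule = match.arg(roc_candidate_rule),
                 fisher_threshold = fisher_threshold,
                 logistic_max_iter = logistic_max_iter,
                 logistic_tol = logistic_tol, level = level),
            class = "tipi_config")
}

.analysis_covariates <- c("menopausal_status", "clinical_t", "clinical_n",
                          "clinical_stage", "hr_status", "her2_category",
                          "grade", "ki67_category", "tils_category",
                          "tipi_group")

#' Run the full TIPI analysis on a cohort
#'
#' Computes SII and TIPI per record, derives the risk-group cut-off from the
#' data by the Youden index (or applies `config$tipi_cutoff` when
#' `fixed_cutoff = TRUE`, e.g. to reproduce a published stratification),
#' then produces: the baseline table with a chi-square/Fisher association
#' test per categorical covariate, Shapiro-Wilk-gated continuous comparisons
#' of TILs and Ki-67 by pCR, the ROC block with DeLong inference and the
#' Youden operating point, pCR rates by risk group with their test, a
#' univariable logistic screen and the prespecified multivariable model.
#' The result is deterministic given the cohort and configuration.
#'
#' @param cohort a `tipi_cohort` (or coercible data frame) with both pCR
#'   classes present and at least 10 records.
#' @param config a [tipi_config()].
#' @param fixed_cutoff if `TRUE`, use `config$tipi_cutoff` for risk grouping
#'   instead of the data-derived Youden cut-off.
#' @return Object of class `tipi_analysis` with elements `baseline`,
#'   `associations`, `continuous_comparisons`, `roc`, `risk_group`,
#'   `univariable`, `multivariable` and `metadata`.
#' @examples
#' coh <- generate_cohort(cohort_sim_config(n = 120, seed = 3))
#' res <- tipi_analysis(coh)
#' res$risk_group$rate_high
#' @export
tipi_analysis <- function(cohort, config = tipi_config(), fixed_cutoff = FALSE) {
  stopifnot(inherits(config, "tipi_config"))
  prov <- attr(cohort, "provenance") %||% "user"
  cohort <- as_cohort(cohort, provenance = prov)
  if (nrow(cohort) < 10) {
    stop_degenerate("cohort too small for analysis (n = ", nrow(cohort),
                    " < 10)")
  }
  if (length(unique(cohort$pcr)) < 2) {
    stop_degenerate("both pCR classes must be present")
  }
  cohort <- score_cohort(cohort, sii_unit_scale = config$sii_unit_scale)

  roc <- tipi_roc(cohort$tipi, cohort$pcr, level = config$level,
                  candidate_rule = config$roc_candidate_rule)
  cutoff <- if (fixed_cutoff) config$tipi_cutoff else roc$youden_cutoff
  cohort$tipi_group <- assign_risk_group(cohort$tipi, cutoff)

  baseline <- summarize_baseline(cohort)

  assoc <- lapply(.analysis_covariates, function(cv) {
    tab <- suppressWarnings(build_contingency(cohort, cv))
    if (nrow(tab$counts) < 2) {
      return(data.frame(variable = cv, method = "none", statistic = NA_real_,
                        df = NA_integer_, p = NA_real_))
    }
    tr <- select_and_test(tab, config$fisher_threshold)
    data.frame(variable = cv, method = tr$method, statistic = tr$statistic,
               df = tr$df, p = tr$p_value, stringsAsFactors = FALSE)
  })
  associations <- do.call(rbind, assoc)
  rownames(associations) <- NULL

  cont <- lapply(c(tils = "stromal_tils_percent", ki67 = "ki67_percent"),
                 function(v) compare_continuous_by_group(cohort[[v]], cohort$pcr))

  grp_tab <- build_contingency(cohort, "tipi_group")
  grp_test <- select_and_test(grp_tab, config$fisher_threshold)
  n_high <- sum(cohort$tipi_group == "high")
  n_low <- sum(cohort$tipi_group == "low")
  risk_group <- list(
    cutoff = cutoff,
    cutoff_source = if (fixed_cutoff) "fixed" else "youden",
    n_low = n_low, n_high = n_high,
    pcr_low = sum(cohort$pcr & cohort$tipi_group == "low"),
    pcr_high = sum(cohort$pcr & cohort$tipi_group == "high"),
    test = grp_test)
  risk_group$rate_low <- if (n_low) risk_group$pcr_low / n_low else NA_real_
  risk_group$rate_high <- if (n_high) risk_group$pcr_high / n_high else NA_real_

  uni <- univariable_screen(cohort)
  multi <- multivariable_model(cohort)

  structure(list(
    baseline = baseline, associations = associations,
    continuous_comparisons = cont, roc = roc, risk_group = risk_group,
    univariable = uni, multivariable = multi,
    cohort = cohort,
    metadata = list(n = nrow(cohort), provenance = prov,
                    cutoff = cutoff,
                    cutoff_source = risk_group$cutoff_source,
                    config = unclass(config),
                    package_version = as.character(utils::packageVersion("tipiscore")))),
    class = "tipi_analysis")
}

#' @export
print.tipi_analysis <- function(x, ...) {
  cat(sprintf("TIPI analysis of %d patients (%s)\n", x$metadata$n,
              x$metadata$provenance))
  cat(sprintf("  Overall pCR rate: %s%% (%d/%d)\n",
              fmt_pct(100 * x$baseline$pcr_rate),
              sum(x$risk_group$pcr_low, x$risk_group$pcr_high), x$metadata$n))
  cat(sprintf("  Risk-group cut-off: %.3f (%s)\n", x$risk_group$cutoff,
              x$risk_group$cutoff_source))
  cat(sprintf("  pCR by TIPI group: high %s%% (%d/%d) vs low %s%% (%d/%d), %s p = %s\n",
              fmt_pct(100 * x$risk_group$rate_high), x$risk_group$pcr_high,
              x$risk_group$n_high, fmt_pct(100 * x$risk_group$rate_low),
              x$risk_group$pcr_low, x$risk_group$n_low,
              x$risk_group$test$method, fmt_p(x$risk_group$test$p_value)))
  cat(sprintf("  AUC %.3f (%d%% CI %.3f-%.3f), p vs 0.5 = %s\n",
              x$roc$auc, round(100 * x$roc$level), x$roc$auc_ci[1],
              x$roc$auc_ci[2], fmt_p(x$roc$auc_p_vs_half)))
  cat("\nMultivariable model:\n")
  print(x$multivariable)
  invisible(x)
}

#' @export
summary.tipi_analysis <- function(object, ...) {
  cat("Baseline association tests:\n")
  a <- object$associations
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-20s %-18s p = %s\n", a$variable[i], a$method[i],
                fmt_p(a$p[i])))
  }
  cat("\nContinuous comparisons (pCR+ vs pCR-):\n")
  for (nm in names(object$continuous_comparisons)) {
    cc <- object$continuous_comparisons[[nm]]
    cat(sprintf("  %-6s %.1f vs %.1f (%s), p = %s\n", nm, cc$mean_pos,
                cc$mean_neg, cc$method, fmt_p(cc$p_value)))
  }
  print(object)
  invisible(object)
}

# Serializable (list-of-numbers) view of a report, used by the JSON and
# markdown renderers and by determinism checks.
report_as_list <- function(x) {
  stopifnot(inherits(x, "tipi_analysis"))
  multi <- x$multivariable
  list(
    n = x$metadata$n,
    provenance = x$metadata$provenance,
    package_version = x$metadata$package_version,
    pcr_rate = x$baseline$pcr_rate,
    baseline_categorical = x$baseline$categorical,
    baseline_continuous = x$baseline$continuous,
    associations = x$associations,
    continuous_comparisons = lapply(x$continuous_comparisons, function(cc)
      cc[c("mean_pos", "mean_neg", "n_pos", "n_neg", "method", "p_value")]),
    roc = list(auc = x$roc$auc, auc_se = x$roc$auc_se, auc_ci = x$roc$auc_ci,
               auc_p_vs_half = x$roc$auc_p_vs_half,
               youden_cutoff = x$roc$youden_cutoff, youden_j = x$roc$youden_j,
               sens_at_cutoff = x$roc$sens_at_cutoff,
               spec_at_cutoff = x$roc$spec_at_cutoff),
    risk_group = x$risk_group[c("cutoff", "cutoff_source", "n_low", "n_high",
                                "pcr_low", "pcr_high", "rate_low", "rate_high")],
    risk_group_p = x$risk_group$test$p_value,
    univariable = x$univariable,
    multivariable = list(terms = multi$terms,
                         stage_wald = multi$stage_wald,
                         omnibus = multi$omnibus,
                         nagelkerke_r2 = multi$nagelkerke_r2,
                         converged = multi$converged))
}

table2_block <- function(x) {
  multi <- x$multivariable
  tab <- multi$terms[-1, , drop = FALSE]
  stage <- grepl("^clinical_stage", tab$term)
  main <- tab[!stage, , drop = FALSE]
  out <- data.frame(
    term = c(main$term, "clinical_stage (joint)"),
    B = c(main$B, NA), SE = c(main$SE, NA),
    Wald = c(main$wald, multi$stage_wald$wald),
    OR = c(main$OR, NA), ci_low = c(main$ci_low, NA),
    ci_high = c(main$ci_high, NA),
    p = c(main$p, multi$stage_wald$p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Render an analysis report to files
#'
#' Writes the report in one or more formats under `dir`: `report.json`
#' (lossless, full precision), `baseline.tsv` + `model.tsv` +
#' `roc_points.tsv` (tab-separated tables), or `report.md` (markdown tables
#' shaped like a clinical baseline table and an adjusted-model table, with
#' p-values rounded to 3 decimals, percentages to 1 and odds ratios to 3 at
#' render time only).
#'
#' @param report a `tipi_analysis`.
#' @param format character vector among `"json"`, `"tsv"`, `"markdown"`.
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, format = "json", dir = ".") {
  stopifnot(inherits(report, "tipi_analysis"))
  bad <- setdiff(format, c("json", "tsv", "markdown"))
  if (length(bad)) stop_usage("unknown format(s): ", paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  if ("json" %in% format) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null")
    written <- c(written, path)
  }
  if ("tsv" %in% format) {
    p1 <- file.path(dir, "baseline.tsv")
    base <- merge(report$baseline$categorical,
                  report$associations[, c("variable", "method", "p")],
                  by = "variable", all.x = TRUE, sort = FALSE)
    utils::write.table(base, p1, sep = "\t", row.names = FALSE, quote = FALSE)
    p2 <- file.path(dir, "model.tsv")
    utils::write.table(table2_block(report), p2, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    p3 <- file.path(dir, "roc_points.tsv")
    utils::write.table(report$roc$points, p3, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, p1, p2, p3)
  }
  if ("markdown" %in% format) {
    path <- file.path(dir, "report.md")
    writeLines(render_markdown(report), path)
    written <- c(written, path)
  }
  invisible(written)
}

render_markdown <- function(x) {
  out <- c(sprintf("# TIPI analysis report (n = %d)", x$metadata$n), "",
           sprintf("Overall pCR rate: %s%%", fmt_pct(100 * x$baseline$pcr_rate)),
           sprintf("Risk-group cut-off: %.3f (%s)", x$risk_group$cutoff,
                   x$risk_group$cutoff_source), "",
           "## Baseline characteristics", "",
           "| Variable | Level | n (%) | pCR+ n (%) | pCR- n (%) | p |",
           "|---|---|---|---|---|---|")
  cat_tab <- x$baseline$categorical
  for (v in unique(cat_tab$variable)) {
    blk <- cat_tab[cat_tab$variable == v, ]
    p <- x$associations$p[x$associations$variable == v]
    p_str <- if (length(p) && !is.na(p[1])) fmt_p(p[1]) else ""
    for (i in seq_len(nrow(blk))) {
      out <- c(out, sprintf("| %s | %s | %d (%s) | %d (%s) | %d (%s) | %s |",
                            if (i == 1) v else "", blk$level[i], blk$n[i],
                            fmt_pct(blk$pct[i]), blk$n_pcr_pos[i],
                            fmt_pct(blk$pct_pcr_pos[i]), blk$n_pcr_neg[i],
                            fmt_pct(blk$pct_pcr_neg[i]),
                            if (i == 1) p_str else ""))
    }
  }
  out <- c(out, "", "## ROC analysis", "",
           sprintf("AUC %.3f (%d%% CI %.3f-%.3f); p vs 0.5 = %s; Youden cut-off %.3f (sensitivity %s%%, specificity %s%%)",
                   x$roc$auc, round(100 * x$roc$level), x$roc$auc_ci[1],
                   x$roc$auc_ci[2], fmt_p(x$roc$auc_p_vs_half),
                   x$roc$youden_cutoff, fmt_pct(100 * x$roc$sens_at_cutoff),
                   fmt_pct(100 * x$roc$spec_at_cutoff)),
           "", "## Multivariable logistic regression", "",
           "| Variable | B | S.E. | Wald | OR (95% CI) | p-Value |",
           "|---|---|---|---|---|---|")
  t2 <- table2_block(x)
  for (i in seq_len(nrow(t2))) {
    or_str <- if (is.na(t2$OR[i])) "-" else
      sprintf("%s (%s-%s)", fmt_or(t2$OR[i]), fmt_or(t2$ci_low[i]),
              fmt_or(t2$ci_high[i]))
    out <- c(out, sprintf("| %s | %s | %s | %.3f | %s | %s |", t2$term[i],
                          if (is.na(t2$B[i])) "-" else sprintf("%.3f", t2$B[i]),
                          if (is.na(t2$SE[i])) "-" else sprintf("%.3f", t2$SE[i]),
                          t2$Wald[i], or_str, fmt_p(t2$p[i])))
  }
  multi <- x$multivariable
  c(out, "",
    sprintf("Omnibus test p = %s; Nagelkerke R^2 = %.3f",
            fmt_p(multi$omnibus$p), multi$nagelkerke_r2))
}
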