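# Group-comparison machinery for the baseline table: covariate-by-pCR
# contingency tables with chi-square / Fisher routing, and Shapiro-Wilk-gated
# continuous comparisons.

new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "tipi_test")
}

#' @export
print.tipi_test <- function(x, ...) {
  cat(sprintf("%s: %sp = %s\n", x$method,
              if (is.na(x$statistic)) "" else
                sprintf("statistic = %.4f, df = %s, ", x$statistic,
                        ifelse(is.na(x$df), "-", x$df)),
              fmt_p(x$p_value)))
  invisible(x)
}

#' Cross-tabulate a categorical covariate against pCR
#'
#' Builds the r x 2 table of covariate level by outcome, columns ordered
#' (pCR+, pCR-). Levels observed zero times are dropped with a warning so the
#' downstream tests see only attainable cells.
#'
#' @param cohort a `tipi_cohort`.
#' @param covariate name of a categorical column (or a derived category:
#'   `ki67_category`, `tils_category`, `tipi_group`).
#' @param levels optional explicit level ordering.
#' @return An object of class `contingency_table`: counts, labels, margins
#'   and the grand total.
#' @export
build_contingency <- function(cohort, covariate, levels = NULL) {
  cohort <- as_cohort(cohort, provenance = attr(cohort, "provenance") %||% "user")
  cats <- baseline_categoricals(cohort)
  if (covariate %in% names(cats)) {
    x <- cats[[covariate]]
  } else if (covariate %in% names(cohort)) {
    x <- cohort[[covariate]]
    if (covariate %in% c(.cohort_continuous, "sii", "tipi") ||
        (is.numeric(x) && length(unique(x)) > 5)) {
      stop_usage("covariate '", covariate, "' is not categorical")
    }
    x <- factor(x)
  } else {
    stop_usage("unknown covariate '", covariate, "'")
  }
  if (!is.null(levels)) x <- factor(as.character(x), levels = levels)
  counts <- table(x, factor(ifelse(cohort$pcr, "pCR+", "pCR-"),
                            levels = c("pCR+", "pCR-")))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("dropping unobserved level(s) of '", covariate, "': ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  as_contingency(unclass(counts)[, , drop = FALSE], variable = covariate)
}

#' Construct a contingency table from a count matrix
#'
#' @param counts matrix of non-negative integer counts, rows = covariate
#'   levels, columns = outcome classes (pCR+ first by convention).
#' @param variable optional covariate name.
#' @return A `contingency_table` object.
#' @export
as_contingency <- function(counts, variable = NA_character_) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_usage("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) rownames(counts) <- paste0("r", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- c("pCR+", "pCR-")[seq_len(ncol(counts))]
  n <- sum(counts)
  if (n < 1) stop_usage("table is empty")
  structure(list(counts = counts,
                 row_labels = rownames(counts), col_labels = colnames(counts),
                 row_totals = rowSums(counts), col_totals = colSums(counts),
                 n = n, variable = variable),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  if (!is.na(x$variable)) cat(sprintf("Contingency table: %s\n", x$variable))
  print(x$counts)
  invisible(x)
}

#' Expected counts under independence
#'
#' @param table a `contingency_table`.
#' @return Matrix of `row_total * col_total / n`.
#' @export
expected_counts <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  outer(table$row_totals, table$col_totals) / table$n
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic (no Yates continuity correction) with the
#' usual `(r-1)(c-1)` degrees of freedom. The uncorrected form is what
#' mainstream clinical software reports for 2 x 2 baseline tables.
#'
#' @param table a `contingency_table` with at least 2 rows and 2 columns.
#' @return A `tipi_test` with `method = "pearson_chi2"`.
#' @export
pearson_chi_square <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (nrow(table$counts) < 2 || ncol(table$counts) < 2) {
    stop_usage("chi-square requires at least a 2x2 table")
  }
  E <- expected_counts(table)
  if (any(E == 0)) stop_degenerate("degenerate table: expected count of zero")
  ht <- suppressWarnings(stats::chisq.test(table$counts, correct = FALSE))
  new_test_result(unname(ht$statistic), unname(ht$parameter),
                  unname(ht$p.value), "pearson_chi2")
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by the probability-mass criterion: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (within a 1 + 1e-7
#' relative tolerance), the convention of mainstream statistical software.
#' A table with a zero margin admits a single configuration and returns
#' p = 1.
#'
#' @param table a 2 x 2 `contingency_table`.
#' @return A `tipi_test` with `method = "fisher_exact_2x2"` (no statistic or
#'   df, as for exact tests).
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (nrow(table$counts) != 2 || ncol(table$counts) != 2) {
    stop_usage("Fisher exact test requires a 2x2 table")
  }
  if (any(table$row_totals == 0) || any(table$col_totals == 0)) {
    p <- 1
  } else {
    p <- stats::fisher.test(table$counts)$p.value
  }
  new_test_result(NA_real_, NA_integer_, p, "fisher_exact_2x2")
}

#' Choose and run the appropriate independence test
#'
#' Routes to [fisher_exact_2x2()] when the table is 2 x 2 and any expected
#' count falls below `fisher_threshold` (the textbook "expected < 5" rule),
#' and to [pearson_chi_square()] otherwise; r x c tables with r > 2 are
#' always tested with Pearson.
#'
#' @param table a `contingency_table`.
#' @param fisher_threshold expected-count threshold for routing (default 5).
#' @return A `tipi_test`; the `method` field records which test ran.
#' @export
select_and_test <- function(table, fisher_threshold = 5) {
  stopifnot(inherits(table, "contingency_table"))
  if (nrow(table$counts) < 2 || ncol(table$counts) < 2) {
    stop_usage("independence test requires at least a 2x2 table")
  }
  is2x2 <- nrow(table$counts) == 2 && ncol(table$counts) == 2
  if (is2x2 && min(expected_counts(table)) < fisher_threshold) {
    fisher_exact_2x2(table)
  } else {
    pearson_chi_square(table)
  }
}

# Shapiro-Wilk normality screen for one group. Samples larger than the
# test's 5000-observation limit are thinned deterministically (every k-th
# order statistic); a zero-variance sample is treated as non-normal.
shapiro_gate <- function(v) {
  if (length(unique(v)) < 3) return(0)
  if (length(v) > 5000) {
    v <- sort(v)[round(seq(1, length(v), length.out = 5000))]
  }
  stats::shapiro.test(v)$p.value
}

#' Compare a continuous variable between pCR groups
#'
#' Normality of each group is assessed by the Shapiro-Wilk test at
#' `alpha`; if both groups are compatible with normality a Welch two-sample
#' t-test is used, otherwise a Mann-Whitney U test (exact for small tie-free
#' samples, normal approximation with tie correction otherwise). The chosen
#' test is recorded in the result.
#'
#' @param values numeric vector.
#' @param groups logical (or two-level) vector aligned with `values`; `TRUE`
#'   marks the pCR-positive group.
#' @param alpha significance level for the normality gate (default 0.05).
#' @param test `"auto"` (the default Shapiro-Wilk gate) or an explicit
#'   `"welch"` / `"mann_whitney"` override.
#' @return List with the group means and ns, the Shapiro-Wilk p-values, the
#'   selected `method` (`"welch_t"` or `"mann_whitney"`), the test statistic
#'   and the two-sided `p_value`.
#' @export
compare_continuous_by_group <- function(values, groups, alpha = 0.05,
                                        test = c("auto", "welch", "mann_whitney")) {
  test <- match.arg(test)
  if (is.factor(groups) || is.character(groups)) {
    lev <- unique(as.character(groups))
    if (length(lev) != 2) stop_usage("'groups' must have exactly two levels")
    groups <- as.character(groups) == lev[1]
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.logical(groups[keep])
  g1 <- values[groups]; g0 <- values[!groups]
  if (length(g1) < 3 || length(g0) < 3) {
    stop_usage("each group needs at least 3 observations")
  }
  sw <- c(shapiro_gate(g1), shapiro_gate(g0))
  use_welch <- switch(test, auto = all(sw > alpha), welch = TRUE,
                      mann_whitney = FALSE)
  if (use_welch) {
    ht <- stats::t.test(g1, g0, var.equal = FALSE)
    method <- "welch_t"; statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    if (stats::var(values) == 0) {
      # all observations identical in both groups: no evidence of a shift
      method <- "mann_whitney"; statistic <- length(g1) * length(g0) / 2; p <- 1
    } else {
      ht <- suppressWarnings(stats::wilcox.test(g1, g0))
      method <- "mann_whitney"; statistic <- unname(ht$statistic); p <- ht$p.value
    }
  }
  list(mean_pos = mean(g1), mean_neg = mean(g0),
       n_pos = length(g1), n_neg = length(g0),
       shapiro_p = sw, method = method, statistic = statistic, p_value = p)
}
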