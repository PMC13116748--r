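# Cohort container: a validated data.frame of pretreatment pathology,
# blood-count and clinical covariates plus the binary pCR outcome, one row
# per patient. Blood counts are interpreted in units of 1e9 cells/L (the
# usual scale in the SII literature); an alternative scale can be declared
# through `sii_unit_scale` in the analysis configuration.

cohort_required_columns <- function() {
  c("patient_id", "age_years", "menopausal_status", "clinical_t",
    "clinical_n", "clinical_stage", "hr_status", "her2_category", "grade",
    "ki67_percent", "stromal_tils_percent", "neutrophils", "lymphocytes",
    "platelets", "pcr")
}

cohort_optional_columns <- function() "tumor_size_mm"

cohort_levels <- function() {
  list(
    menopausal_status = c("premenopausal", "postmenopausal"),
    clinical_t        = c("cT1", "cT2", "cT3_4"),
    clinical_n        = c("cN0", "cN1", "cN2_3"),
    clinical_stage    = c("IIA", "IIB", "III"),
    hr_status         = c("negative", "positive"),
    her2_category     = c("IHC3plus", "IHC2plus_ISHpos")
  )
}

.cohort_continuous <- c("age_years", "tumor_size_mm", "ki67_percent",
                        "stromal_tils_percent", "neutrophils", "lymphocytes",
                        "platelets")

#' Construct a validated patient cohort
#'
#' Coerces a data frame of patient records to the canonical cohort layout and
#' enforces the record-level invariants: Ki-67 and stromal-TIL percentages in
#' \[0, 100\], strictly positive blood counts and age, Nottingham grade in
#' \{1, 2, 3\}, recognised category labels, a logical (or 0/1) pCR outcome and
#' unique patient identifiers. `tumor_size_mm` is optional and may be `NA`;
#' every other field is required per record.
#'
#' @param df data frame containing the columns listed by
#'   [cohort_required_columns()] (and optionally `tumor_size_mm`).
#' @param provenance free-text tag recording where the cohort came from,
#'   e.g. `"synthetic seed=7"` or `"fixture:table1"`.
#' @return The cohort as a data frame of class `tipi_cohort`, row order
#'   preserved, with a `provenance` attribute.
#' @examples
#' coh <- generate_cohort(cohort_sim_config(n = 20, seed = 1))
#' nrow(as_cohort(coh))
#' @export
as_cohort <- function(df, provenance = "user") {
  if (!is.data.frame(df)) stop_usage("cohort input must be a data frame")
  missing_cols <- setdiff(cohort_required_columns(), names(df))
  if (length(missing_cols)) {
    stop_validation("missing required column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!nrow(df)) stop_validation("cohort must contain at least one record")

  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    dup <- unique(df$patient_id[duplicated(df$patient_id)])
    stop_validation("duplicate patient_id: ", paste(dup, collapse = ", "))
  }
  if (!"tumor_size_mm" %in% names(df)) df$tumor_size_mm <- NA_real_

  num_cols <- c(.cohort_continuous, "grade")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (col != "tumor_size_mm") bad <- union(bad, which(is.na(df[[col]])))
    if (length(bad)) {
      stop_validation("row ", bad[1], ": field '", col,
                      "' is missing or not numeric")
    }
    df[[col]] <- v
  }

  pcr <- df$pcr
  if (is.character(pcr)) pcr <- suppressWarnings(as.numeric(pcr))
  if (is.numeric(pcr)) {
    if (any(is.na(pcr)) || !all(pcr %in% c(0, 1))) {
      stop_validation("row ", which(is.na(pcr) | !pcr %in% c(0, 1))[1],
                      ": field 'pcr' must be logical or 0/1")
    }
    pcr <- pcr == 1
  }
  if (!is.logical(pcr) || anyNA(pcr)) {
    stop_validation("field 'pcr' must be logical or 0/1 with no missing values")
  }
  df$pcr <- pcr

  lv <- cohort_levels()
  for (col in names(lv)) {
    x <- as.character(df[[col]])
    bad <- which(!x %in% lv[[col]])
    if (length(bad)) {
      stop_validation("row ", bad[1], ": field '", col, "' has value '",
                      x[bad[1]], "'; expected one of ",
                      paste(lv[[col]], collapse = ", "))
    }
    df[[col]] <- x
  }

  check_range <- function(col, lo, hi, lo_strict = FALSE) {
    v <- df[[col]]
    ok <- !is.na(v) & (if (lo_strict) v > lo else v >= lo) & v <= hi
    ok[is.na(v)] <- col == "tumor_size_mm"
    if (!all(ok)) {
      stop_validation("row ", which(!ok)[1], ": field '", col, "' value ",
                      v[which(!ok)[1]], " outside valid range")
    }
  }
  check_range("ki67_percent", 0, 100)
  check_range("stromal_tils_percent", 0, 100)
  check_range("age_years", 0, Inf, lo_strict = TRUE)
  check_range("tumor_size_mm", 0, Inf, lo_strict = TRUE)
  for (col in c("neutrophils", "lymphocytes", "platelets")) {
    check_range(col, 0, Inf, lo_strict = TRUE)
  }
  if (!all(df$grade %in% c(1, 2, 3))) {
    stop_validation("row ", which(!df$grade %in% c(1, 2, 3))[1],
                    ": field 'grade' must be 1, 2 or 3")
  }
  df$grade <- as.integer(df$grade)

  rownames(df) <- NULL
  class(df) <- c("tipi_cohort", "data.frame")
  attr(df, "provenance") <- provenance
  df
}

#' Read a patient cohort from a delimited text file
#'
#' The interchange format is comma-delimited UTF-8 with a header row, decimal
#' points, and the pCR outcome encoded as 0/1. Column names in the file can
#' be remapped onto the canonical names through `schema`.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names (names of the vector) to the column names used in the file
#'   (values), e.g. `c(ki67_percent = "KI67")`.
#' @return A validated [as_cohort()] object; row order is that of the file.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      stop_usage("schema must be a named character vector (canonical = file)")
    }
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        stop_validation("schema column '", src, "' (for '", canon,
                        "') not present in file")
      }
      names(df)[names(df) == src] <- canon
    }
  }
  as_cohort(df, provenance = paste0("file:", path))
}

#' Write a patient cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' `x` field for field (continuous values at full double precision; pCR as
#' 0/1).
#'
#' @param cohort a `tipi_cohort` (or coercible data frame).
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort, provenance = attr(cohort, "provenance") %||% "user")
  out <- as.data.frame(cohort)
  out$pcr <- as.integer(out$pcr)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Baseline characteristics table
#'
#' Summarises a cohort in the layout of a clinical baseline table: continuous
#' variables as mean, SD, median and range, overall and within each pCR
#' stratum; categorical variables as counts with the percentage of the cohort
#' at each level and the within-level pCR split. Ki-67 is additionally
#' dichotomised at 20% and stromal TILs banded at <10% / 10--40% / >40%, the
#' conventional descriptive groupings.
#'
#' @param cohort a `tipi_cohort`.
#' @return A list of class `tipi_baseline` with elements `continuous` and
#'   `categorical` (data frames), `pcr_rate` (overall fraction achieving pCR)
#'   and `n`. The SD of a single observation is reported as `NA`.
#' @export
summarize_baseline <- function(cohort) {
  cohort <- as_cohort(cohort, provenance = attr(cohort, "provenance") %||% "user")
  pos <- cohort$pcr

  cont_one <- function(v, label, group) {
    v <- v[!is.na(v)]
    data.frame(variable = label, group = group, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  }
  cont_vars <- intersect(c(.cohort_continuous, "sii", "tipi"), names(cohort))
  continuous <- do.call(rbind, lapply(cont_vars, function(cv) {
    rbind(cont_one(cohort[[cv]], cv, "overall"),
          cont_one(cohort[[cv]][pos], cv, "pcr_pos"),
          cont_one(cohort[[cv]][!pos], cv, "pcr_neg"))
  }))

  cats <- baseline_categoricals(cohort)
  categorical <- do.call(rbind, lapply(names(cats), function(cv) {
    x <- cats[[cv]]
    lev <- levels(x)
    do.call(rbind, lapply(lev, function(l) {
      n_tot <- sum(x == l, na.rm = TRUE)
      n_pos <- sum(x == l & pos, na.rm = TRUE)
      n_neg <- n_tot - n_pos
      data.frame(variable = cv, level = l, n = n_tot,
                 pct = 100 * n_tot / nrow(cohort),
                 n_pcr_pos = n_pos,
                 pct_pcr_pos = if (n_tot) 100 * n_pos / n_tot else NA_real_,
                 n_pcr_neg = n_neg,
                 pct_pcr_neg = if (n_tot) 100 * n_neg / n_tot else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(categorical) <- NULL

  structure(list(continuous = continuous, categorical = categorical,
                 pcr_rate = mean(pos), n = nrow(cohort)),
            class = "tipi_baseline")
}

# Categorical view of a cohort: factors in their canonical level order,
# including the derived Ki-67 and TIL bands and, when present, the TIPI
# risk group.
baseline_categoricals <- function(cohort) {
  lv <- cohort_levels()
  out <- list()
  for (col in names(lv)) out[[col]] <- factor(cohort[[col]], levels = lv[[col]])
  out$grade <- factor(cohort$grade, levels = sort(unique(cohort$grade)))
  out$ki67_category <- factor(ifelse(cohort$ki67_percent <= 20, "<=20%", ">20%"),
                              levels = c("<=20%", ">20%"))
  tl <- cohort$stromal_tils_percent
  out$tils_category <- factor(
    ifelse(tl < 10, "low(<10%)", ifelse(tl <= 40, "intermediate(10-40%)", "high(>40%)")),
    levels = c("low(<10%)", "intermediate(10-40%)", "high(>40%)"))
  if ("tipi_group" %in% names(cohort)) {
    out$tipi_group <- factor(cohort$tipi_group, levels = c("low", "high"))
  }
  out
}

#' @export
print.tipi_baseline <- function(x, ...) {
  cat(sprintf("Baseline characteristics, n = %d (pCR rate %s%%)\n\n",
              x$n, fmt_pct(100 * x$pcr_rate)))
  cont <- x$continuous[x$continuous$group == "overall", ]
  for (i in seq_len(nrow(cont))) {
    cat(sprintf("  %-22s mean %.1f (SD %.1f), median %.1f, range %.1f-%.1f\n",
                cont$variable[i], cont$mean[i], cont$sd[i], cont$median[i],
                cont$min[i], cont$max[i]))
  }
  cat("\n")
  for (v in unique(x$categorical$variable)) {
    blk <- x$categorical[x$categorical$variable == v, ]
    cat(sprintf("  %s:\n", v))
    for (i in seq_len(nrow(blk))) {
      cat(sprintf("    %-22s %3d (%s%%)  pCR+ %d (%s%%)\n", blk$level[i],
                  blk$n[i], fmt_pct(blk$pct[i]), blk$n_pcr_pos[i],
                  fmt_pct(blk$pct_pcr_pos[i])))
    }
  }
  invisible(x)
}
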