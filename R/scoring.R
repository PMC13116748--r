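# TIPI score: (Ki-67% + stromal TILs% + 10 * grade) / (1 + SII/1000).
# The numerator aggregates tumor proliferation, local immune infiltration
# and histological aggressiveness; the denominator down-weights the score
# under high systemic inflammatory burden as measured by the SII.

#' Systemic immune-inflammation index (SII)
#'
#' SII = platelets x neutrophils / lymphocytes, from a pretreatment complete
#' blood count. With counts in 1e9 cells/L the index is on its conventional
#' scale (typically a few hundred to a few thousand).
#'
#' @param neutrophils,lymphocytes,platelets strictly positive counts
#'   (1e9 cells/L); vectors are recycled to a common length.
#' @param unit_scale multiplicative factor applied to the resulting index,
#'   for inputs recorded on another scale (default 1 for 1e9/L counts).
#' @return Numeric vector of SII values.
#' @examples
#' compute_sii(2, 2, 500)   # 500
#' @export
compute_sii <- function(neutrophils, lymphocytes, platelets, unit_scale = 1) {
  for (nm in c("neutrophils", "lymphocytes", "platelets")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(v <= 0)) {
      stop_usage("'", nm, "' must be strictly positive")
    }
  }
  unit_scale * platelets * neutrophils / lymphocytes
}

#' TIPI composite score
#'
#' Combines the four pretreatment components into the dimensionless
#' Tumor-Immune-Proliferation-Inflammation score
#' \deqn{(Ki67 + TILs + 10 \cdot grade) / (1 + SII/1000).}
#' Grade is weighted by 10 to place the ordinal on a scale comparable to the
#' two percentages; SII is divided by 1000 so that systemic inflammation
#' attenuates rather than dominates the score.
#'
#' @param ki67_percent Ki-67 labelling index in \[0, 100\].
#' @param stromal_tils_percent stromal TIL percentage in \[0, 100\].
#' @param grade Nottingham histological grade, 1, 2 or 3.
#' @param sii systemic immune-inflammation index, strictly positive.
#' @return Numeric vector of TIPI scores (strictly positive for grade >= 1).
#' @examples
#' compute_tipi(50, 20, 3, 1000)  # 50
#' @export
compute_tipi <- function(ki67_percent, stromal_tils_percent, grade, sii) {
  if (!is.numeric(ki67_percent) || anyNA(ki67_percent) ||
      any(ki67_percent < 0 | ki67_percent > 100)) {
    stop_usage("'ki67_percent' must lie in [0, 100]")
  }
  if (!is.numeric(stromal_tils_percent) || anyNA(stromal_tils_percent) ||
      any(stromal_tils_percent < 0 | stromal_tils_percent > 100)) {
    stop_usage("'stromal_tils_percent' must lie in [0, 100]")
  }
  if (anyNA(grade) || !all(grade %in% c(1, 2, 3))) {
    stop_usage("'grade' must be 1, 2 or 3")
  }
  if (!is.numeric(sii) || anyNA(sii) || any(sii <= 0)) {
    stop_usage("'sii' must be strictly positive")
  }
  (ki67_percent + stromal_tils_percent + 10 * grade) / (1 + sii / 1000)
}

#' Assign TIPI risk groups at a cut-off
#'
#' A score strictly above the cut-off is "high"; a score at or below it is
#' "low" (boundary inclusive on the low side, the "<= cut-off" convention).
#' The cut-off is a data-derived quantity, typically the Youden-optimal value
#' from [youden_optimal()] on the cohort being analysed; it is not part of
#' the score definition.
#'
#' @param tipi numeric vector of TIPI scores.
#' @param cutoff risk-group boundary on the TIPI scale.
#' @return Factor with levels `low`, `high`.
#' @export
assign_risk_group <- function(tipi, cutoff) {
  if (!is.numeric(tipi) || anyNA(tipi) || any(!is.finite(tipi))) {
    stop_usage("'tipi' must be finite numeric")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff)) {
    stop_usage("'cutoff' must be a single finite number")
  }
  factor(ifelse(tipi > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Add SII, TIPI and risk-group columns to a cohort
#'
#' @param cohort a `tipi_cohort`.
#' @param cutoff optional risk-group boundary; when supplied a `tipi_group`
#'   column is added via [assign_risk_group()].
#' @param sii_unit_scale passed to [compute_sii()].
#' @return The cohort with `sii` and `tipi` columns (and `tipi_group` when
#'   `cutoff` is given).
#' @export
score_cohort <- function(cohort, cutoff = NULL, sii_unit_scale = 1) {
  cohort <- as_cohort(cohort, provenance = attr(cohort, "provenance") %||% "user")
  prov <- attr(cohort, "provenance")
  cohort$sii <- compute_sii(cohort$neutrophils, cohort$lymphocytes,
                            cohort$platelets, unit_scale = sii_unit_scale)
  cohort$tipi <- compute_tipi(cohort$ki67_percent, cohort$stromal_tils_percent,
                              cohort$grade, cohort$sii)
  if (!is.null(cutoff)) {
    cohort$tipi_group <- assign_risk_group(cohort$tipi, cutoff)
  }
  class(cohort) <- c("tipi_cohort", "data.frame")
  attr(cohort, "provenance") <- prov
  cohort
}
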