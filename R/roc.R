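# Empirical ROC analysis for a continuous score against a binary outcome.
# A record is called positive when its score is strictly above the threshold,
# consistent with the "high (> cut-off)" risk-group convention; the AUC is
# computed by the Mann-Whitney rank formula and its sampling variance by the
# DeLong placement-value decomposition.

check_roc_input <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_usage("scores and labels differ in length")
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels) || any(!is.finite(scores))) {
    stop_usage("scores and labels must be finite and non-missing")
  }
  if (!any(labels) || all(labels)) {
    stop_degenerate("both outcome classes must be present for ROC analysis")
  }
  list(scores = as.numeric(scores), labels = labels)
}

#' Empirical ROC curve points
#'
#' Candidate thresholds are, by default, the midpoints between consecutive
#' distinct sorted scores plus sentinels below the minimum and above the
#' maximum (`"midpoint"` rule); alternatively the observed score values
#' themselves plus sentinels (`"observed"` rule). At threshold t a record is
#' test-positive iff its score exceeds t.
#'
#' @param scores numeric predictor; higher values predict the positive class.
#' @param labels logical outcome (`TRUE` = pCR achieved).
#' @param candidate_rule `"midpoint"` (default) or `"observed"`.
#' @return Data frame with columns `threshold`, `sensitivity`, `specificity`,
#'   ordered by increasing threshold.
#' @export
roc_points <- function(scores, labels, candidate_rule = c("midpoint", "observed")) {
  candidate_rule <- match.arg(candidate_rule)
  inp <- check_roc_input(scores, labels)
  scores <- inp$scores; labels <- inp$labels
  u <- sort(unique(scores))
  thr <- switch(candidate_rule,
    midpoint = c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                 u[length(u)] + 1),
    observed = c(u[1] - 1, u, u[length(u)] + 1))
  sp <- sort(scores[labels]); sn <- sort(scores[!labels])
  np <- length(sp); nn <- length(sn)
  # count of scores <= t via findInterval on the sorted class samples
  sens <- (np - findInterval(thr, sp)) / np
  spec <- findInterval(thr, sn) / nn
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC = (concordant positive-negative pairs + half the ties) divided by the
#' number of pairs; identical to the trapezoidal area under the empirical
#' curve. Computed from midranks in O(n log n).
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  inp <- check_roc_input(scores, labels)
  r <- rank(inp$scores)
  np <- sum(inp$labels); nn <- sum(!inp$labels)
  (sum(r[inp$labels]) - np * (np + 1) / 2) / (np * nn)
}

#' DeLong inference for the empirical AUC
#'
#' Nonparametric variance of the AUC from the placement values: for each
#' positive, the fraction of negatives it beats (ties half-weighted), and
#' symmetrically for each negative. The AUC variance is the sum of the two
#' placement-value sample variances scaled by their class sizes. The Wald
#' confidence interval is clipped to \[0, 1\] and the two-sided p-value tests
#' the null AUC = 0.5.
#'
#' @inheritParams roc_points
#' @param level confidence level (default 0.95).
#' @return List with `auc`, `se`, `ci` (length-2), `p_vs_half` and `level`.
#'   With zero placement variance (e.g. perfect separation) the interval
#'   collapses to the point estimate with a warning.
#' @export
delong_inference <- function(scores, labels, level = 0.95) {
  inp <- check_roc_input(scores, labels)
  scores <- inp$scores; labels <- inp$labels
  np <- sum(labels); nn <- sum(!labels)
  if (np < 2 || nn < 2) stop_usage("DeLong inference needs >= 2 records per class")
  auc <- auc_mann_whitney(scores, labels)
  # midrank identity: placement of positive i among negatives equals
  # (overall midrank - within-positive midrank) / n_neg
  r_all <- rank(scores)
  v10 <- (r_all[labels] - rank(scores[labels])) / nn
  v01 <- 1 - (r_all[!labels] - rank(scores[!labels])) / np
  s10 <- stats::var(v10); s01 <- stats::var(v01)
  se <- sqrt(s10 / np + s01 / nn)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (se == 0) {
    warning("zero DeLong variance: confidence interval collapses to the point estimate")
    ci <- c(auc, auc)
    p <- if (auc == 0.5) 1 else 0
  } else {
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
    p <- 2 * stats::pnorm(-abs((auc - 0.5) / se))
  }
  list(auc = auc, se = se, ci = ci, p_vs_half = p, level = level)
}

#' Youden-index optimal cut-off
#'
#' Maximises J = sensitivity + specificity - 1 over the candidate thresholds
#' of [roc_points()]. Ties in J are broken in favour of higher sensitivity,
#' then of the lower cut-off.
#'
#' @inheritParams roc_points
#' @return List with `cutoff`, `youden_j`, `sensitivity` and `specificity`
#'   at the selected threshold.
#' @export
youden_optimal <- function(scores, labels, candidate_rule = c("midpoint", "observed")) {
  pts <- roc_points(scores, labels, candidate_rule)
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-pts$sensitivity[best], pts$threshold[best])][1]
  list(cutoff = pts$threshold[best], youden_j = j[best],
       sensitivity = pts$sensitivity[best], specificity = pts$specificity[best])
}

#' Confusion matrix and operating characteristics at a cut-off
#'
#' A record is called positive iff its score is strictly above the cut-off
#' (consistent with [assign_risk_group()]).
#'
#' @inheritParams roc_points
#' @param cutoff decision threshold on the score scale.
#' @return List with `tp`, `fp`, `tn`, `fn` and `sensitivity`,
#'   `specificity`, `ppv`, `npv` (predictive values `NA` when their
#'   denominator is zero).
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  inp <- check_roc_input(scores, labels)
  call_pos <- inp$scores > cutoff
  tp <- sum(call_pos & inp$labels);  fn <- sum(!call_pos & inp$labels)
  fp <- sum(call_pos & !inp$labels); tn <- sum(!call_pos & !inp$labels)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Full ROC analysis of a score
#'
#' Convenience wrapper combining [roc_points()], [auc_mann_whitney()],
#' [delong_inference()] and [youden_optimal()] into one result object.
#'
#' @inheritParams delong_inference
#' @param candidate_rule passed to [roc_points()].
#' @return Object of class `tipi_roc` with the curve points, AUC with CI and
#'   p versus 0.5, and the Youden-optimal operating point.
#' @export
tipi_roc <- function(scores, labels, level = 0.95,
                     candidate_rule = c("midpoint", "observed")) {
  candidate_rule <- match.arg(candidate_rule)
  pts <- roc_points(scores, labels, candidate_rule)
  dl <- delong_inference(scores, labels, level)
  yo <- youden_optimal(scores, labels, candidate_rule)
  structure(list(points = pts, auc = dl$auc, auc_se = dl$se, auc_ci = dl$ci,
                 auc_p_vs_half = dl$p_vs_half, level = level,
                 youden_cutoff = yo$cutoff, youden_j = yo$youden_j,
                 sens_at_cutoff = yo$sensitivity, spec_at_cutoff = yo$specificity,
                 n_pos = sum(as.logical(labels)), n_neg = sum(!as.logical(labels))),
            class = "tipi_roc")
}

#' @export
print.tipi_roc <- function(x, ...) {
  cat(sprintf("ROC analysis (%d positive / %d negative)\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f (%d%% CI %.3f-%.3f), p vs 0.5 = %s\n",
              x$auc, round(100 * x$level), x$auc_ci[1], x$auc_ci[2],
              fmt_p(x$auc_p_vs_half)))
  cat(sprintf("  Youden cut-off %.3f (J = %.3f): sensitivity %s%%, specificity %s%%\n",
              x$youden_cutoff, x$youden_j, fmt_pct(100 * x$sens_at_cutoff),
              fmt_pct(100 * x$spec_at_cutoff)))
  invisible(x)
}
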