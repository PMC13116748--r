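# Binary logistic regression with the clinical reporting surface: per-term
# B, SE, Wald chi-square, OR with 95% CI and p; model-level omnibus
# likelihood-ratio test and Nagelkerke R^2. Estimation is maximum likelihood
# (IRLS via stats::glm); quasi-complete separation is detected from
# diverging coefficients and flagged rather than silently reported.

#' Fit a binary logistic regression with clinical reporting
#'
#' @param formula model formula with a logical (or 0/1) response.
#' @param data data frame (e.g. a `tipi_cohort`).
#' @param max_iter maximum IRLS iterations (default 100).
#' @param tol convergence tolerance on the relative deviance change
#'   (default 1e-10).
#' @param level confidence level for the Wald odds-ratio intervals; the 95%
#'   level uses z = 1.96 exactly, matching conventional reporting.
#' @return Object of class `tipi_logit`: a coefficient table (`term`, `B`,
#'   `SE`, `wald`, `OR`, `ci_low`, `ci_high`, `p`), log-likelihoods of the
#'   null and fitted models, the omnibus likelihood-ratio test, Nagelkerke
#'   R^2, `converged` flag (FALSE under non-convergence or detected
#'   separation, with a `diagnostic` message), iteration count and `n`.
#' @examples
#' coh <- generate_cohort(cohort_sim_config(n = 200, seed = 1))
#' fit_logistic(pcr ~ hr_status, coh)
#' @export
fit_logistic <- function(formula, data, max_iter = 100, tol = 1e-10,
                         level = 0.95) {
  saturated_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        saturated_warn <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  y <- fit$y
  if (!all(y %in% c(0, 1))) stop_usage("response must be logical or 0/1")
  n <- length(y)
  if (n <= length(stats::coef(fit))) {
    stop_usage("more parameters than observations")
  }
  sm <- summary(fit)$coefficients
  beta <- sm[, 1]; se <- sm[, 2]
  z_ci <- if (abs(level - 0.95) < 1e-12) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  wald <- (beta / se)^2
  tab <- data.frame(term = rownames(sm), B = unname(beta), SE = unname(se),
                    wald = unname(wald), OR = unname(exp(beta)),
                    ci_low = unname(exp(beta - z_ci * se)),
                    ci_high = unname(exp(beta + z_ci * se)),
                    p = unname(stats::pchisq(wald, df = 1, lower.tail = FALSE)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  ll_model <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  ll_null <- as.numeric(stats::logLik(null_fit))
  df_omni <- length(beta) - 1
  chi2 <- max(0, 2 * (ll_model - ll_null))
  omnibus <- list(chi2 = chi2, df = df_omni,
                  p = if (df_omni > 0) stats::pchisq(chi2, df_omni, lower.tail = FALSE) else 1)

  separated <- (length(beta) > 1 && any(abs(beta[-1]) > 15)) || saturated_warn
  converged <- isTRUE(fit$converged) && !separated
  diagnostic <- if (!isTRUE(fit$converged)) {
    "IRLS did not converge within the iteration limit"
  } else if (separated) {
    "diverging fit (|B| > 15 or fitted probabilities of 0/1): quasi-complete separation suspected"
  } else NA_character_

  res <- structure(list(terms = tab, loglik_null = ll_null,
                        loglik_model = ll_model, omnibus = omnibus,
                        nagelkerke_r2 = NA_real_, converged = converged,
                        diagnostic = diagnostic, n_iter = fit$iter, n = n,
                        level = level, formula = formula, glm_fit = fit),
                   class = "tipi_logit")
  res$nagelkerke_r2 <- nagelkerke_r2(res)
  res
}

#' Omnibus likelihood-ratio test of model coefficients
#'
#' Chi-square `2 * (loglik_model - loglik_null)` on as many degrees of
#' freedom as non-intercept parameters, against the intercept-only model.
#'
#' @param fit a `tipi_logit`.
#' @return List with `chi2`, `df`, `p`.
#' @export
omnibus_lr_test <- function(fit) {
  stopifnot(inherits(fit, "tipi_logit"))
  fit$omnibus
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell `1 - exp(2 (l0 - l1) / n)` rescaled by its maximum
#' `1 - exp(2 l0 / n)` so the measure reaches 1 for perfect prediction;
#' 0 for the null model.
#'
#' @param fit a `tipi_logit`.
#' @return Value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(fit) {
  stopifnot(inherits(fit, "tipi_logit"))
  l0 <- fit$loglik_null; l1 <- fit$loglik_model; n <- fit$n
  r2_cs <- 1 - exp(2 * (l0 - l1) / n)
  denom <- 1 - exp(2 * l0 / n)
  if (denom <= 0) return(0)
  min(1, max(0, r2_cs / denom))
}

#' @export
coef.tipi_logit <- function(object, ...) {
  stats::setNames(object$terms$B, object$terms$term)
}

#' @export
print.tipi_logit <- function(x, ...) {
  cat(sprintf("Logistic regression (n = %d%s)\n", x$n,
              if (x$converged) "" else "; NOT CONVERGED"))
  if (!is.na(x$diagnostic)) cat("  ", x$diagnostic, "\n", sep = "")
  tab <- x$terms
  cat(sprintf("  %-28s %8s %7s %7s %22s %7s\n",
              "term", "B", "S.E.", "Wald", "OR (95% CI)", "p"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s %8.3f %7.3f %7.3f %8s (%s-%s) %7s\n", tab$term[i],
                tab$B[i], tab$SE[i], tab$wald[i], fmt_or(tab$OR[i]),
                fmt_or(tab$ci_low[i]), fmt_or(tab$ci_high[i]), fmt_p(tab$p[i])))
  }
  cat(sprintf("  Omnibus chi2 = %.3f (df %d), p = %s; Nagelkerke R2 = %.3f\n",
              x$omnibus$chi2, x$omnibus$df, fmt_p(x$omnibus$p), x$nagelkerke_r2))
  invisible(x)
}

# Modelling view of a cohort: factors releveled so reported ORs are oriented
# the conventional way (high vs low TIPI, HR negativity vs positivity,
# grade 3 vs grade 2, stage IIB/III vs IIA).
model_frame_cohort <- function(cohort, cutoff = NULL) {
  if (!"tipi_group" %in% names(cohort)) {
    if (is.null(cutoff)) stop_usage("cohort has no tipi_group; supply a cutoff")
    cohort <- score_cohort(cohort, cutoff = cutoff)
  }
  data.frame(
    pcr = cohort$pcr,
    tipi_group = factor(cohort$tipi_group, levels = c("low", "high")),
    hr_status = factor(cohort$hr_status, levels = c("positive", "negative")),
    grade = factor(cohort$grade),
    clinical_stage = factor(cohort$clinical_stage, levels = c("IIA", "IIB", "III")),
    her2_category = factor(cohort$her2_category,
                           levels = c("IHC2plus_ISHpos", "IHC3plus")),
    menopausal_status = factor(cohort$menopausal_status,
                               levels = c("premenopausal", "postmenopausal")),
    stringsAsFactors = FALSE)
}

#' Univariable logistic screen
#'
#' One single-predictor logistic model per listed term, summarised as OR
#' with CI and Wald p; rows are returned in the input term order. A fit with
#' suspected separation is flagged in the `converged` column.
#'
#' @param cohort a scored `tipi_cohort` (needs `tipi_group` when that term
#'   is screened, or supply `cutoff`).
#' @param terms character vector of predictor names.
#' @param cutoff optional TIPI cut-off used to derive `tipi_group` if absent.
#' @return Data frame with one row per non-reference level of each term.
#' @export
univariable_screen <- function(cohort,
                               terms = c("tipi_group", "hr_status", "grade",
                                         "clinical_stage"),
                               cutoff = NULL) {
  mfc <- model_frame_cohort(cohort, cutoff)
  out <- lapply(terms, function(tm) {
    if (!tm %in% names(mfc)) stop_usage("unknown model term '", tm, "'")
    fit <- fit_logistic(stats::as.formula(paste("pcr ~", tm)), mfc)
    tab <- fit$terms[-1, , drop = FALSE]
    cbind(data.frame(variable = tm, stringsAsFactors = FALSE), tab,
          data.frame(converged = fit$converged))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multivariable model of pCR (Enter method)
#'
#' Fits the prespecified adjusted model with all four terms entered
#' simultaneously: TIPI risk group (high vs low), hormone-receptor status
#' (negative vs positive), histological grade (3 vs 2; grade-1 records,
#' should any exist, are excluded with a message) and clinical stage as a
#' three-level factor referenced at IIA. Stage is additionally summarised by
#' a joint multi-degree-of-freedom Wald test, the form in which a
#' multi-level adjustment variable is conventionally reported.
#'
#' @inheritParams univariable_screen
#' @return A `tipi_logit` with an extra `stage_wald` element
#'   (`wald`, `df`, `p`) and class `tipi_multilogit`.
#' @export
multivariable_model <- function(cohort, cutoff = NULL) {
  mfc <- model_frame_cohort(cohort, cutoff)
  if (any(mfc$grade == "1")) {
    message("excluding ", sum(mfc$grade == "1"),
            " grade-1 record(s) from the grade 3 vs 2 comparison")
    mfc <- mfc[mfc$grade != "1", , drop = FALSE]
  }
  mfc$grade <- factor(as.character(mfc$grade), levels = c("2", "3"))
  fit <- fit_logistic(pcr ~ tipi_group + hr_status + grade + clinical_stage, mfc)

  stage_idx <- grep("^clinical_stage", fit$terms$term)
  if (length(stage_idx)) {
    b <- fit$terms$B[stage_idx]
    V <- stats::vcov(fit$glm_fit)[fit$terms$term[stage_idx],
                                  fit$terms$term[stage_idx], drop = FALSE]
    w <- as.numeric(t(b) %*% solve(V, b))
    fit$stage_wald <- list(wald = w, df = length(stage_idx),
                           p = stats::pchisq(w, length(stage_idx), lower.tail = FALSE))
  } else {
    fit$stage_wald <- list(wald = NA_real_, df = 0L, p = NA_real_)
  }
  class(fit) <- c("tipi_multilogit", "tipi_logit")
  fit
}

#' @export
print.tipi_multilogit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  Clinical stage (joint): Wald = %.3f (df %d), p = %s\n",
              x$stage_wald$wald, x$stage_wald$df, fmt_p(x$stage_wald$p)))
  invisible(x)
}
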