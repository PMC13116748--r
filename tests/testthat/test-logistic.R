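test_that("intercept-only fit recovers the log-odds of the prevalence", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_logistic(y ~ 1, data.frame(y = y))
  expect_equal(unname(coef(fit)), log(0.3 / 0.7), tolerance = 1e-8)
  omni <- omnibus_lr_test(fit)
  expect_equal(omni$chi2, 0)
  expect_equal(omni$p, 1)
  expect_equal(nagelkerke_r2(fit), 0, tolerance = 1e-10)
})

test_that("single binary predictor reproduces the 2x2 cross-product OR", {
  # hormone-receptor counts: negative 17 pCR+ / 9 pCR-, positive 17 / 32
  df <- data.frame(
    pcr = rep(c(1, 0, 1, 0), c(17, 9, 17, 32)),
    hr_neg = rep(c(1, 1, 0, 0), c(17, 9, 17, 32)))
  fit <- fit_logistic(pcr ~ hr_neg, df)
  expect_equal(fit$terms$OR[2], (17 * 32) / (9 * 17), tolerance = 1e-6)
  # saturated model: fitted probabilities equal observed cell proportions
  p_hat <- unique(round(fitted(fit$glm_fit), 10))
  expect_setequal(p_hat, round(c(17 / 26, 17 / 49), 10))
  # omnibus adds a predictor: chi2 strictly positive here
  expect_gt(omnibus_lr_test(fit)$chi2, 0)
})

test_that("coefficient table is internally consistent", {
  set.seed(3)
  df <- data.frame(x1 = rnorm(300), x2 = rbinom(300, 1, 0.4))
  df$y <- runif(300) < plogis(-0.5 + 0.8 * df$x1 + 0.6 * df$x2)
  fit <- fit_logistic(y ~ x1 + x2, df)
  expect_equal(fit$terms$OR, exp(fit$terms$B))
  expect_equal(fit$terms$ci_low, exp(fit$terms$B - 1.96 * fit$terms$SE))
  expect_equal(fit$terms$ci_high, exp(fit$terms$B + 1.96 * fit$terms$SE))
  expect_equal(fit$terms$wald, (fit$terms$B / fit$terms$SE)^2)
  expect_equal(fit$omnibus$chi2,
               2 * (fit$loglik_model - fit$loglik_null))
  # score equations hold at the optimum
  X <- model.matrix(fit$glm_fit)
  resid_score <- crossprod(X, fit$glm_fit$y - fitted(fit$glm_fit))
  expect_lt(max(abs(resid_score)), 1e-6)
})

test_that("standard errors match the numerical Hessian", {
  set.seed(5)
  df <- data.frame(x1 = rnorm(500), x2 = rnorm(500))
  df$y <- runif(500) < plogis(0.3 + 0.7 * df$x1 - 0.5 * df$x2)
  fit <- fit_logistic(y ~ x1 + x2, df)
  X <- model.matrix(fit$glm_fit); y <- fit$glm_fit$y
  nll <- function(b) -sum(y * (X %*% b) - log1p(exp(X %*% b)))
  b_hat <- coef(fit)
  h <- 1e-5
  H <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    e_i <- e_j <- rep(0, 3); e_i[i] <- h; e_j[j] <- h
    H[i, j] <- (nll(b_hat + e_i + e_j) - nll(b_hat + e_i) -
                  nll(b_hat + e_j) + nll(b_hat)) / h^2
  }
  se_num <- sqrt(diag(solve((H + t(H)) / 2)))
  expect_equal(fit$terms$SE, se_num, tolerance = 1e-4)
})

test_that("maximum likelihood recovers known generating coefficients", {
  set.seed(9)
  n <- 20000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- runif(n) < plogis(-1.0 + 0.9 * x1 + 1.3 * x2)
  fit <- fit_logistic(y ~ x1 + x2, data.frame(y, x1, x2))
  expect_lt(max(abs(coef(fit) - c(-1.0, 0.9, 1.3))), 0.1)
  expect_true(fit$converged)
})

test_that("Nagelkerke R2 matches direct formula evaluation", {
  set.seed(15)
  df <- data.frame(x = rnorm(20))
  df$y <- runif(20) < plogis(df$x)
  if (length(unique(df$y)) == 1) df$y[1] <- !df$y[1]
  fit <- fit_logistic(y ~ x, df)
  l0 <- fit$loglik_null; l1 <- fit$loglik_model; n <- fit$n
  r2_cs <- 1 - exp(2 * (l0 - l1) / n)
  expect_equal(nagelkerke_r2(fit), r2_cs / (1 - exp(2 * l0 / n)),
               tolerance = 1e-10)
  expect_gte(fit$nagelkerke_r2, 0); expect_lte(fit$nagelkerke_r2, 1)
})

test_that("near-perfect prediction drives Nagelkerke R2 toward 1 and flags separation", {
  df <- data.frame(x = c(rnorm(50, -3), rnorm(50, 3)),
                   y = rep(c(FALSE, TRUE), each = 50))
  fit <- suppressWarnings(fit_logistic(y ~ x, df))
  expect_gt(fit$nagelkerke_r2, 0.9)
  # fully separated data are flagged, never silently reported
  df2 <- data.frame(x = c(1:20, 31:50), y = rep(c(FALSE, TRUE), each = 20))
  fit2 <- suppressWarnings(fit_logistic(y ~ x, df2))
  expect_false(fit2$converged)
  expect_match(fit2$diagnostic, "separation|converge")
})

test_that("omnibus null p-values are near-uniform", {
  set.seed(19)
  ps <- replicate(500, {
    x <- rnorm(300)
    y <- rbinom(300, 1, 0.45)
    fit_logistic(y ~ x, data.frame(x, y))$omnibus$p
  })
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.07)
})

test_that("univariable screen returns one block per term in input order", {
  coh <- generate_cohort(cohort_sim_config(n = 400, seed = 21))
  scr <- univariable_screen(coh, terms = c("hr_status", "tipi_group",
                                           "grade", "clinical_stage"))
  expect_equal(unique(scr$variable),
               c("hr_status", "tipi_group", "grade", "clinical_stage"))
  expect_equal(nrow(scr), 5)  # 3 binaries + 2 stage dummies
  # binary-term OR equals the cross-product ratio of its 2x2 table
  m <- table(coh$hr_status == "negative", coh$pcr)
  or_tab <- (m["TRUE", "TRUE"] * m["FALSE", "FALSE"]) /
    (m["TRUE", "FALSE"] * m["FALSE", "TRUE"])
  expect_equal(scr$OR[scr$variable == "hr_status"], unname(or_tab),
               tolerance = 1e-6)
  expect_error(univariable_screen(coh, terms = "nonexistent"),
               class = "tipi_usage_error")
})

test_that("multivariable model recovers generating odds ratios", {
  beta <- c(-1.5, 0.888, 1.326, 1.038, 0, 0)
  rec <- generate_recovery_dataset(beta, n = 10000, seed = 25)
  fit <- multivariable_model(rec$cohort)
  tab <- fit$terms
  or_of <- function(term) tab$OR[tab$term == term]
  expect_lt(abs(or_of("tipi_grouphigh") / exp(0.888) - 1), 0.15)
  expect_lt(abs(or_of("hr_statusnegative") / exp(1.326) - 1), 0.15)
  expect_lt(abs(or_of("grade3") / exp(1.038) - 1), 0.15)
  # stage entered as a 3-level factor summarised by a joint 2-df Wald test
  expect_equal(fit$stage_wald$df, 2)
  expect_gt(fit$stage_wald$p, 0.001)
  expect_equal(fit$omnibus$df, 5)
  # rows appear in the prespecified order
  expect_equal(tab$term[2:4], c("tipi_grouphigh", "hr_statusnegative", "grade3"))
})

test_that("dropping a model term changes the omnibus degrees of freedom", {
  coh <- generate_cohort(cohort_sim_config(n = 500, seed = 27))
  mfc <- tipiscore:::model_frame_cohort(coh)
  full <- fit_logistic(pcr ~ tipi_group + hr_status + grade + clinical_stage, mfc)
  red <- fit_logistic(pcr ~ tipi_group + hr_status + grade, mfc)
  expect_equal(full$omnibus$df - red$omnibus$df, 2)
  expect_gte(full$loglik_model, red$loglik_model)
})
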