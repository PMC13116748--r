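table1_counts <- list(
  menopause = matrix(c(20, 24, 14, 17), 2, 2, byrow = TRUE,
                     dimnames = list(c("pre", "post"), c("pCR+", "pCR-"))),
  hr    = matrix(c(17, 9, 17, 32), 2, 2, byrow = TRUE),
  her2  = matrix(c(31, 29, 3, 12), 2, 2, byrow = TRUE),
  grade = matrix(c(10, 23, 24, 18), 2, 2, byrow = TRUE),
  tipi  = matrix(c(7, 20, 27, 21), 2, 2, byrow = TRUE),
  ki67  = matrix(c(1, 5, 33, 36), 2, 2, byrow = TRUE))

test_that("contingency construction preserves counts and totals", {
  fx <- generate_table1_fixture()
  tab <- build_contingency(fx, "tipi_group")
  expect_equal(unname(tab$counts), matrix(c(7, 20, 27, 21), 2, 2, byrow = TRUE))
  expect_equal(unname(tab$row_totals), c(27, 48))
  expect_equal(unname(tab$col_totals), c(34, 41))
  expect_equal(tab$n, 75)
  # permuting record order leaves counts unchanged
  perm <- fx[rev(seq_len(nrow(fx))), ]
  tab2 <- build_contingency(as_cohort(perm), "tipi_group")
  expect_equal(tab2$counts, tab$counts)
  # single observed level collapses to one row with a warning
  one <- as_cohort(tiny_cohort_df(4))
  one$menopausal_status <- "premenopausal"
  expect_warning(t1 <- build_contingency(as_cohort(one), "menopausal_status"),
                 "postmenopausal")
  expect_equal(nrow(t1$counts), 1)
  expect_error(build_contingency(fx, "age_years"), class = "tipi_usage_error")
})

test_that("expected counts follow the margin product rule", {
  tab <- as_contingency(table1_counts$tipi)
  E <- expected_counts(tab)
  expect_equal(E[1, 1], 27 * 34 / 75)  # 12.24
  expect_equal(unname(rowSums(E)), unname(tab$row_totals))
  expect_equal(unname(colSums(E)), unname(tab$col_totals))
  expect_equal(unname(expected_counts(as_contingency(matrix(5, 2, 2)))),
               matrix(5, 2, 2))
})

test_that("uncorrected Pearson chi-square reproduces published 2x2 p-values", {
  p_of <- function(m) pearson_chi_square(as_contingency(m))$p_value
  expect_equal(round(p_of(table1_counts$hr), 3), 0.011)
  expect_equal(round(p_of(table1_counts$tipi), 3), 0.011)
  expect_equal(round(p_of(table1_counts$her2), 3), 0.028)
  expect_equal(round(p_of(table1_counts$grade), 3), 0.020)
  expect_equal(round(p_of(table1_counts$menopause), 3), 0.980)
})

test_that("proportional rows give a zero statistic and p = 1", {
  tr <- pearson_chi_square(as_contingency(matrix(c(10, 20, 5, 10), 2, 2,
                                                 byrow = TRUE)))
  expect_equal(tr$statistic, 0)
  expect_equal(tr$p_value, 1)
  expect_error(pearson_chi_square(as_contingency(matrix(c(0, 0, 3, 4), 2, 2,
                                                        byrow = TRUE))),
               class = "tipi_degenerate_error")
})

test_that("Pearson statistic is invariant under row/column permutation", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(sample(1:30, 6), 3, 2)
    a <- pearson_chi_square(as_contingency(m))
    b <- pearson_chi_square(as_contingency(m[c(2, 3, 1), c(2, 1)]))
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("Fisher exact matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(as_contingency(diag(1, 2)))$p_value, 1)
  expect_equal(fisher_exact_2x2(as_contingency(matrix(c(0, 0, 3, 4), 2, 2,
                                                      byrow = TRUE)))$p_value, 1)
  set.seed(41)
  for (i in 1:200) {
    m <- random_2x2()
    p <- fisher_exact_2x2(as_contingency(m))$p_value
    expect_equal(p, oracle_fisher_2x2(m), tolerance = 1e-10)
    expect_gt(p, 0); expect_lte(p, 1)
  }
  expect_error(fisher_exact_2x2(as_contingency(matrix(1, 3, 2))),
               class = "tipi_usage_error")
})

test_that("test selector routes by table shape and expected counts", {
  r_ki67 <- select_and_test(as_contingency(table1_counts$ki67))
  expect_equal(r_ki67$method, "fisher_exact_2x2")  # min expected 2.72 < 5
  r_men <- select_and_test(as_contingency(table1_counts$menopause))
  expect_equal(r_men$method, "pearson_chi2")
  expect_equal(round(r_men$p_value, 3), 0.980)
  # r x 2 tables with r > 2 always go to Pearson, sparse or not
  m3 <- matrix(c(1, 2, 2, 1, 30, 30), 3, 2, byrow = TRUE)
  expect_equal(select_and_test(as_contingency(m3))$method, "pearson_chi2")
  # threshold is configurable
  expect_equal(select_and_test(as_contingency(table1_counts$ki67),
                               fisher_threshold = 2)$method, "pearson_chi2")
})

test_that("Pearson p-values are near-uniform under the 2x2 null", {
  set.seed(99)
  n <- 500
  ps <- replicate(2000, {
    x <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    m <- table(factor(x, 0:1), factor(y, 0:1))
    pearson_chi_square(as_contingency(unclass(m)))$p_value
  })
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.05)
})

test_that("continuous comparison gates on normality and records its choice", {
  set.seed(13)
  g1 <- rnorm(200, 0); g0 <- rnorm(200, 0)
  r <- compare_continuous_by_group(c(g1, g0), rep(c(TRUE, FALSE), each = 200))
  expect_equal(r$method, "welch_t")
  skew1 <- rexp(200); skew0 <- rexp(200)
  r2 <- compare_continuous_by_group(c(skew1, skew0),
                                    rep(c(TRUE, FALSE), each = 200))
  expect_equal(r2$method, "mann_whitney")
  expect_error(compare_continuous_by_group(1:4, c(TRUE, TRUE, FALSE, FALSE)),
               class = "tipi_usage_error")
})

test_that("identical samples in both groups yield p = 1", {
  v <- rep(5, 20)
  r <- compare_continuous_by_group(v, rep(c(TRUE, FALSE), 10))
  expect_equal(r$p_value, 1)
  same <- c(1, 2, 3, 4, 5)
  r2 <- compare_continuous_by_group(c(same, same), rep(c(TRUE, FALSE), each = 5),
                                    test = "welch")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
})

test_that("well-separated groups are detected with overwhelming evidence", {
  set.seed(77)
  v <- c(rnorm(5000, 0), rnorm(5000, 1))
  g <- rep(c(FALSE, TRUE), each = 5000)
  r <- compare_continuous_by_group(v, g)
  expect_lt(r$p_value, 1e-10)
  expect_gt(r$mean_pos - r$mean_neg, 0.9)
})

test_that("Mann-Whitney p agrees with exact permutation enumeration", {
  set.seed(55)
  for (i in 1:25) {
    m <- sample(4:8, 1); n <- sample(4:8, 1)
    v <- sample(seq_len(200), m + n)  # distinct -> tie-free
    g1 <- v[seq_len(m)]; g0 <- v[-seq_len(m)]
    r <- compare_continuous_by_group(c(g1, g0),
                                     rep(c(TRUE, FALSE), c(m, n)),
                                     test = "mann_whitney")
    expect_equal(r$p_value, oracle_mann_whitney_exact(g1, g0),
                 tolerance = 1e-12)
  }
})
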