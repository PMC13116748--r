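# Independent oracles used to cross-check the package implementations.
# Each is written from the defining formula, not from the code path it
# verifies.

# Two-sided Fisher p by direct enumeration over all tables with the observed
# margins, using binomial coefficients only.
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- probs[ks == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by explicit pair counting over all positive-negative pairs.
oracle_auc_pairs <- function(scores, labels) {
  sp <- scores[labels]; sn <- scores[!labels]
  tot <- 0
  for (x in sp) tot <- tot + sum(x > sn) + 0.5 * sum(x == sn)
  tot / (length(sp) * length(sn))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (tie-free data, small samples).
oracle_mann_whitney_exact <- function(g1, g0) {
  all_v <- c(g1, g0)
  stopifnot(!anyDuplicated(all_v))
  m <- length(g1)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(all_v), m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_lo <- mean(u_all <= u_obs); p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Random small contingency table with non-degenerate margins.
random_2x2 <- function(max_cell = 12) {
  repeat {
    m <- matrix(sample(0:max_cell, 4, replace = TRUE), 2, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# Minimal hand-built valid cohort rows for validation tests.
tiny_cohort_df <- function(n = 3) {
  data.frame(
    patient_id = paste0("P", seq_len(n)),
    age_years = 45 + seq_len(n),
    menopausal_status = rep(c("premenopausal", "postmenopausal"), length.out = n),
    tumor_size_mm = 25,
    clinical_t = rep(c("cT1", "cT2", "cT3_4"), length.out = n),
    clinical_n = rep(c("cN0", "cN1", "cN2_3"), length.out = n),
    clinical_stage = rep(c("IIA", "IIB", "III"), length.out = n),
    hr_status = rep(c("negative", "positive"), length.out = n),
    her2_category = rep(c("IHC3plus", "IHC2plus_ISHpos"), length.out = n),
    grade = rep(c(2L, 3L), length.out = n),
    ki67_percent = 40 + seq_len(n),
    stromal_tils_percent = 15 + seq_len(n),
    neutrophils = 4, lymphocytes = 2, platelets = 280,
    pcr = rep(c(TRUE, FALSE), length.out = n),
    stringsAsFactors = FALSE)
}
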