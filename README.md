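# tipiscore

Predicting pathological complete response (pCR) to neoadjuvant chemotherapy
plus dual anti-HER2 blockade in HER2-positive breast cancer is still done
largely from fragmented single markers. `tipiscore` implements a composite
pretreatment biomarker — the Tumor-Immune-Proliferation-Inflammation (TIPI)
score — together with the complete statistical pipeline a clinical study
uses to evaluate such a score, and a synthetic-cohort generator so that
every stage of the pipeline is testable without patient-level data. It is
aimed at biostatisticians and clinical researchers who want to compute,
stratify by, or re-derive cut-offs for this class of composite index.

## The score

From routine pretreatment data — the Ki-67 proliferation index (%), the
stromal tumor-infiltrating lymphocyte percentage (TILs, %), the Nottingham
histological grade (1–3), and a complete blood count — the package computes
the systemic immune-inflammation index

    SII = platelets × neutrophils / lymphocytes        (counts in 10⁹/L)

and the composite score

    TIPI = (Ki-67% + TILs% + 10·grade) / (1 + SII/1000).

The numerator aggregates tumor chemosensitivity (Ki-67), host antitumor
immunity (TILs) and morphological aggressiveness (grade, weighted ×10 to
match the percentage scale); the denominator attenuates the score under high
systemic inflammatory burden. Patients are stratified at a **data-derived**
cut-off (Youden index on the cohort's ROC curve); a score strictly above the
cut-off is "high" risk group, at or below it "low".

## The pipeline

`tipi_analysis()` runs the full evaluation on a validated cohort:

* baseline table with per-covariate association tests — uncorrected Pearson
  chi-square, routed to Fisher's exact test when a 2×2 table has any
  expected count < 5;
* Shapiro–Wilk-gated continuous comparisons (Welch t / Mann–Whitney U) of
  TILs and Ki-67 by pCR;
* empirical ROC curve, Mann–Whitney AUC with DeLong 95% CI and test versus
  0.5, Youden-optimal cut-off with its operating point;
* pCR rates by TIPI risk group with their test;
* univariable logistic screen and the prespecified multivariable model
  (high TIPI, HR negativity, grade 3 vs 2, clinical stage vs IIA) reported
  as B, S.E., Wald, OR (95% CI), p, with the omnibus likelihood-ratio test
  and Nagelkerke R².

## Worked example

```r
library(tipiscore)

coh <- generate_cohort(cohort_sim_config(n = 150, seed = 7))
res <- tipi_analysis(coh)
print(res)
```

```
TIPI analysis of 150 patients (synthetic seed=7 n=150)
  Overall pCR rate: 47.3% (71/150)
  Risk-group cut-off: 52.891 (youden)
  pCR by TIPI group: high 61.3% (49/80) vs low 31.4% (22/70), pearson_chi2 p = <0.001
  AUC 0.656 (95% CI 0.569-0.744), p vs 0.5 = <0.001

Multivariable model:
Logistic regression (n = 150)
  term                                B    S.E.    Wald            OR (95% CI)       p
  (Intercept)                    -1.984   0.447  19.717    0.137 (0.057-0.330)  <0.001
  tipi_grouphigh                  1.173   0.384   9.357    3.232 (1.524-6.854)   0.002
  hr_statusnegative               1.051   0.377   7.752    2.859 (1.365-5.990)   0.005
  grade3                          1.237   0.400   9.577    3.444 (1.574-7.537)   0.002
  clinical_stageIIB               0.022   0.572   0.002    1.023 (0.333-3.141)   0.969
  clinical_stageIII              -0.041   0.423   0.010    0.959 (0.419-2.198)   0.922
  Omnibus chi2 = 33.524 (df 5), p = <0.001; Nagelkerke R2 = 0.267
  Clinical stage (joint): Wald = 0.015 (df 2), p = 0.993
```

Reading the output: of 150 simulated patients, 47.3% achieved pCR. The
Youden-optimal TIPI cut-off for this cohort is 52.9 (on synthetic data the
score scale depends on the simulated blood counts — the cut-off is always
cohort-specific). Above the cut-off the pCR rate roughly doubles (61.3% vs
31.4%), and in the adjusted model high TIPI, HR negativity and grade 3 each
carry an odds ratio near 3, mirroring the generator's built-in effects.

A deterministic 75-patient reconstruction of a published baseline table is
available as `generate_table1_fixture()`; analysing it at the fixed
historical cut-off reproduces that study's printed rates exactly:

```r
res <- tipi_analysis(generate_table1_fixture(), fixed_cutoff = TRUE)
res$risk_group[c("rate_high", "rate_low")]   # 0.5625 (27/48), 0.2593 (7/27)
```

Reports can be written with `render_report(res, c("json","tsv","markdown"), "out/")`,
and a thin command-line front end is provided in `inst/scripts/tipi.R`
(subcommands `analyze`, `score`, `synth`).

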