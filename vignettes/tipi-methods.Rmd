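---
title: "Methods: the TIPI composite score and its evaluation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the TIPI composite score and its evaluation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipiscore)
```

## The problem and the model

In HER2-positive breast cancer treated with neoadjuvant chemotherapy plus
dual anti-HER2 blockade, pathological complete response (pCR — no residual
invasive tumor in breast or excised nodes, ypT0/is ypN0) is a strong
surrogate for long-term outcome, yet no single pretreatment marker predicts
it well. The TIPI score is a heuristic composite of four routinely
available quantities:

$$\mathrm{TIPI} = \frac{\text{Ki-67\%} + \text{TILs\%} + 10\cdot\text{grade}}
                      {1 + \mathrm{SII}/1000},
\qquad
\mathrm{SII} = \frac{\text{platelets}\times\text{neutrophils}}
                    {\text{lymphocytes}}.$$

The weighting is deliberately interpretable rather than data-optimised:
grade (ordinal 1–3) is multiplied by 10 to sit on a scale comparable to the
two percentages, and the SII is divided by 1000 so that systemic
inflammation attenuates the score without dominating it. Higher values
indicate a biology — proliferative, immune-infiltrated, low systemic
inflammation — expected to favour response.

Two conventions matter downstream and are applied consistently everywhere:
blood counts are interpreted in $10^9$/L (the usual scale in the SII
literature; `sii_unit_scale` in `tipi_config()` declares any other scale),
and a score strictly **above** a cut-off is "high" risk, with the boundary
value assigned to "low" (the $\le$ cut-off convention). With counts in
$10^9$/L, typical SII values of 300–1500 give denominators of roughly
1.3–2.5 and TIPI values well above 10 whenever Ki-67 exceeds 20%; any
published cut-off is therefore treated strictly as a cohort-specific
constant. The formula is implemented literally as stated above; the package
never rescales components to force agreement with an external cut-off, and
`tipi_analysis()` re-derives the cut-off on every new cohort by default.

## Statistical pipeline

`tipi_analysis()` reproduces the full evaluation a clinical study applies
to such a score.

**Association tests.** Each categorical covariate is cross-tabulated
against pCR. 2×2 tables use the *uncorrected* Pearson chi-square — the form
that reproduces conventionally reported baseline-table p-values; Yates'
correction is deliberately not applied. A 2×2 table with any expected count
below 5 (the textbook rule; threshold configurable) is routed to Fisher's
exact test, two-sided by the probability-mass criterion with the standard
$1+10^{-7}$ relative tolerance for floating-point ties. Tables with more
than two rows are always tested with Pearson ($df=(r-1)(c-1)$); no exact
$r\times c$ test is provided, and no multiplicity correction is applied
(none is conventional for a descriptive baseline table).

**Continuous comparisons.** Each group is screened with the Shapiro–Wilk
test at $\alpha = 0.05$ (samples above the test's 5000-observation limit
are thinned deterministically over the order statistics; zero-variance
samples count as non-normal). If both groups pass, a Welch t-test is used;
otherwise a Mann–Whitney U test, exact for small tie-free samples and a
normal approximation with tie correction otherwise — the convention of
mainstream software, and the one under which the small-sample p-value
coincides with exact permutation enumeration.

**ROC analysis.** Candidate thresholds are midpoints between consecutive
distinct scores plus sentinels beyond the range (an `observed`-value rule
is available via `roc_candidate_rule`, since published cut-offs may follow
either convention). The AUC is computed by the Mann–Whitney rank formula
(identical to the trapezoidal area), its variance by the DeLong
placement-value decomposition via the midrank identity, the 95% CI as a
Wald interval clipped to $[0,1]$, and the p-value as a two-sided z-test of
AUC = 0.5 — the natural reading of a p-value printed next to an AUC.
The Youden cut-off maximises $J = \text{sens} + \text{spec} - 1$; ties are
broken toward higher sensitivity, then the lower cut-off. Perfect
separation gives zero DeLong variance; the interval collapses to the point
estimate with a warning rather than failing.

**Logistic models.** Fitting is maximum likelihood by IRLS (via
`stats::glm`, tolerance $10^{-10}$, 100 iterations), reported in the
clinical convention: B, S.E., Wald $=(B/SE)^2$, OR $=e^B$ with
$e^{B \pm 1.96\,SE}$ bounds (the 95% level uses 1.96 exactly), Wald p on 1
df. Model fit is summarised by the omnibus likelihood-ratio chi-square
against the intercept-only model and Nagelkerke's
$R^2 = R^2_{CS}/(1 - e^{2\ell_0/n})$ with
$R^2_{CS} = 1 - e^{2(\ell_0-\ell_1)/n}$. No penalisation is used;
quasi-complete separation is detected (diverging coefficients, $|B|>15$,
or fitted probabilities numerically 0/1) and flagged in the result —
never silently reported as a valid estimate. The multivariable model enters
all four prespecified terms simultaneously (no selection): high vs low
TIPI, HR-negative vs positive, grade 3 vs 2, and clinical stage as a
three-level factor referenced at IIA, additionally summarised by a joint
2-df Wald test, the form in which a multi-level adjustment covariate is
conventionally printed without an OR.

## The synthetic-cohort generator

`generate_cohort()` emulates the structure of the motivating 75-patient
cohort. Categorical marginals default to the published frequencies
(premenopausal 0.587, HR-positive 0.653, IHC 3+ 0.80, grade 3 0.56, stage
0.507/0.187/0.306, and the corresponding T and N distributions). Continuous
families are implementation choices constrained only by published moments:

* age — Normal(46.6, 11.1) truncated to [24, 78] years. The truncation is
  asymmetric, so the realised mean is 47.1 rather than 46.6; the
  parameterisation keeps the published mean/SD as the latent parameters
  and accepts this ~0.5-year bias, a documented emulation limitation.
* tumour size — Normal(28.8, 15.7) mm truncated positive.
* Ki-67 — 100·Beta(2.4, 2.6), mean 48%, covering the observed ≤20%/>20%
  split.
* TILs — a two-component Beta mixture, 0.62·Beta(1.2, 12) +
  0.38·Beta(3, 5) scaled to percent: right-skewed, concentrated at low
  values, mean ≈ 20%, populating all three conventional bands
  (<10 / 10–40 / >40%).
* CBC — neutrophils LogNormal(log 4, 0.3), lymphocytes LogNormal(log 2,
  0.3), platelets Normal(280, 60) truncated positive, all $10^9$/L. No SII
  summary statistics were published, so these are chosen as typical adult
  values; consequently the realised TIPI scale (and any Youden cut-off on
  it) is a property of the simulation, not of the original cohort.

The outcome is drawn from a logistic model on high TIPI (median split of
the realised scores), HR negativity, grade 3 and stage, with default
log-odds effects 0.888, 1.326, 1.038 and 0 — the adjusted coefficients of
the motivating analysis used as generating truth — and an intercept tuned
by `uniroot` on the realised linear predictors so the expected prevalence
is 0.453. Covariates are sampled independently; the only dependence in the
data is the one the outcome model induces. Passing tests on these cohorts
therefore demonstrates correctness of the *machinery* (scoring, testing,
ROC, regression) and calibration under the stated generating model — not
that real HER2-positive cohorts have this joint structure, nor that the
score's discrimination on real data matches the simulated one.

Sampling-stream order is fixed (categoricals, then age, size, Ki-67, TILs
mixture, CBC, then the outcome uniforms; truncated normals use one
inverse-CDF uniform per draw) so a seed is stable across versions, and the
caller's RNG state is saved and restored.

`generate_table1_fixture()` is different in kind: a deterministic 75-record
reconstruction that matches every published variable-by-pCR margin exactly.
The joint distribution across variables is *not* recoverable from published
margins; the fixture therefore assigns levels within each outcome stratum
by fixed per-variable shuffles (arbitrary but deterministic joints, and
decorrelated so the fixture does not exhibit artificial collinearity).
Component values are synthetic placeholders engineered so the scoring
module itself places every record on its published side of the 11.41
cut-off — low-arm blood counts are deliberately far outside physiological
range and are labelled as such. The fixture supports exactly the quantities
derivable from printed counts (rates, operating points, 2×2 tests); its
continuous summaries and multivariable estimates are artefacts of the
placeholder values.

## Numerical and design choices

* Boundary handling: `assign_risk_group()` is strict-above; a score equal
  to the cut-off is low risk.
* Degenerate inputs: analyses refuse cohorts with n < 10 or a single
  outcome class (a distinct condition class, exit code 3 in the CLI);
  validation failures name the offending row and field (exit code 2).
* Expected-count zero makes a chi-square table degenerate and is an error,
  not a silent NaN.
* Missing values: only `tumor_size_mm` may be missing; it is excluded
  listwise from summaries. Records missing any analysis field are rejected
  at validation, mirroring the exclusion of incomplete records in the
  motivating study.
* Interchange format: comma-delimited UTF-8 with header, decimal points,
  pCR as 0/1; `read_cohort(write_cohort(x))` is the identity on all fields.
* Rounding happens only at render time (p to 3 decimals, percentages to 1,
  ORs to 3); all stored numbers are full precision.
* Problem sizes in the test suite (e.g. 2000-table null calibrations,
  n = 20000–100000 consistency checks, 2000 bootstrap resamples) were
  chosen to make sampling error a small fraction of each tolerance while
  keeping the whole suite under a minute on one core.

## Known limitations

* The generator simulates no covariate correlations (e.g. stage with tumour
  size, TILs with grade) beyond outcome-induced dependence.
* No exact r×c (Freeman–Halton) test: published three-level p-values
  computed with such a test will not match Pearson values on the same
  counts.
* The DeLong interval is a Wald construction; its clipping to [0, 1] is a
  pragmatic convention, and small-sample coverage inherits Wald behaviour.
* Alternative composite inflammation indices (NLR, MLR, SIRI, PIV) are out
  of scope, as are survival endpoints and residual-disease grading.
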