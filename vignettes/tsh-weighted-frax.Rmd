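---
title: "TSH-weighted fracture risk assessment: model, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TSH-weighted fracture risk assessment: model, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tshfrax)
```

## The problem

Patients with differentiated thyroid carcinoma (DTC) receive levothyroxine
after thyroidectomy at doses that suppress serum TSH, because TSH drives
residual tumour growth. The same suppression removes TSH's restraining
effect on osteoclasts, so these patients lose bone faster than their age
and sex would predict. FRAX-style calculators estimate the 10-year
probability of a major osteoporotic fracture (MOF) and of a hip fracture
(HF) from age, sex, BMI and a handful of clinical risk flags, optionally
sharpened by a femoral DXA T-score — but they carry no thyroid input. When
a DXA measurement is not (yet) available, a plain "without BMD" FRAX entry
therefore treats a deeply suppressed 48-year-old like any other
48-year-old.

`tshfrax` implements the remedy this package is built around: convert the
degree of TSH suppression into **added years of age** and run the
BMD-free calculation at that *effective age*. Deep suppression below the
assay detection limit (0.008 µIU/mL; µIU/mL ≡ mIU/L) adds 20 years;
euthyroid levels above 2 µIU/mL add nothing; six intermediate bands
interpolate in steps (see `default_tsh_table()`).

## The weighting table and its boundary conventions

The weighting is a step function, not a smooth curve: it mirrors how the
levels are used clinically (banded suppression targets) and avoids
claiming more resolution than the evidence supports. Two boundary points
(exactly 0.008 and exactly 0.1 µIU/mL) are not assigned by the verbal
description the bands come from. We close every such gap **on the
lower-TSH side**, i.e. the ambiguous point receives the larger penalty:
`[0.008, 0.1] → +15`, `(0.1, 0.2] → +10`, and so on. This is the
conservative reading — at an ambiguous boundary the patient is assigned
the higher risk — and the whole table is replaceable via
`as_tsh_table()`, which validates disjointness, full coverage of
(0, ∞), and monotonicity at load.

Effective age is capped at 90 years (`effective_age(..., cap = 90)`),
because published fracture calculators define their probabilities on a
40–90 year domain; an 80-year-old with undetectable TSH would otherwise
be scored at 100. Whether the original clinical procedure capped at 90 is
unknown; the cap is this package's own choice, logged whenever it binds.
Ages between 20 and 40 are passed through unweighted or weighted as the
table dictates; the bundled risk model accepts the full 20–90 range.

## The surrogate risk model

The true FRAX engine is proprietary, so the package separates the
*interface* (three computation modes returning percent probabilities at
0.1 resolution) from the *engine*. When the input CSV carries
probabilities obtained from the real calculator, `attach_risks(source =
"precomputed")` passes them through untouched. Otherwise a **surrogate**
is used: per endpoint, an additive logistic model

\[
\mathrm{logit}(p) = \beta_0 + \beta_a \cdot \text{age}^{*} +
\beta_f \cdot \text{female} + \beta_b \cdot \text{BMI} +
\beta_t \cdot (T + 1) + \textstyle\sum_k \beta_k \cdot \text{flag}_k,
\]

where age\* is the effective age in the `with_tsh` mode and the
chronological age otherwise, and the T-score term participates only in
the `with_bmd` mode. Measuring the T-score effect relative to −1 (the
osteopenia threshold) makes the modes coincide for a subject at the upper
edge of normal bone mass, which keeps the intercept interpretable across
modes. Because the weighting adds zero years above TSH 2 µIU/mL, the
`with_tsh` and `no_bmd` modes coincide *exactly* there — a structural
identity the tests assert.

Sign constraints are enforced at load (`validate_coefficients()`): risk
must rise with age and with every flag, and must not rise with BMI or
T-score. Default magnitudes were fixed once so that the default synthetic
cohort's median risks land where a middle-aged East Asian clinical cohort
typically sits (median PMOF ≈ 2–3%, PHF ≈ 0.2–0.5% in the BMD-free
mode). The surrogate carries **no claim of numerical equivalence to
FRAX**; it exists so that the pipeline, its diagnostics, and its tests
are runnable end to end, and every coefficient is overridable from a
YAML/JSON config (`read_coefficients()`).

Outputs are rounded to one decimal in percent, the resolution of the web
calculator this mimics. That discreteness matters downstream: optimal
cutoffs then fall on midpoints between adjacent one-decimal values (2.15,
4.15, …), and tied scores are common, which is exactly the regime the
diagnostic code is written and tested for.

## Diagnostic evaluation conventions

The gold standard for osteoporosis is the DXA T-score at or below a
configurable threshold, default −2.5 (the WHO definition; `t ≥ −1` is
normal, the open interval between is osteopenia — both boundaries
asserted in tests). Conventions, each a deliberate choice:

* **Candidate thresholds** are midpoints between consecutive distinct
  scores plus `±Inf` sentinels — the convention of standard statistical
  software, and the only one under which published midpoint cutoffs can
  arise.
* **Prediction rule** is `score ≥ cutoff ⇒ positive`: higher predicted
  fracture risk points toward osteoporosis. The opposite orientation is
  clinically meaningless here.
* **AUC** is the trapezoid over the empirical curve, which equals the
  tie-corrected rank statistic \(P(X>Y) + \tfrac12 P(X=Y)\); the test
  suite verifies that identity to 1e−12 against brute-force pair counting
  on a thousand random instances.
* **Youden cutoff** maximizes \(J = \text{sens} + \text{spec} − 1\); ties
  (within 1e−12, to absorb floating-point noise in the fractions) break
  toward the **smallest** cutoff, which favours sensitivity. Ties are
  common with one-decimal scores, so the choice is consequential; it is
  logged when it fires.
* **Undefined ratios** (0/0 in PPV or NPV) are reported as `NA` with a
  warning, never silently as 0.
* `counts_from_rates()` inverts rounded published rates to integer
  confusion matrices; it warns when a rate is not a 3-decimal rounding of
  any integer-count ratio at the stated class sizes — the useful
  definition of "inconsistent report".
* DeLong-style AUC confidence intervals are provided
  (`roc_auc_ci()`, cross-checked against `pROC`) but are deliberately
  outside the acceptance surface: published CI values for this kind of
  analysis are frequently on inconsistent scales, and ours validate only
  against the independent reference implementation.

## Group statistics

Categorical comparisons use the uncorrected Pearson chi-square by default
(`correct = FALSE`) — the convention under which published group
comparisons of this kind reproduce exactly — with the Yates correction
available by flag, and Fisher's exact test for sparse 2×2 tables.
Two-group continuous comparisons use the Mann–Whitney U with midrank
ties; the p-value is exact by enumeration when both sides have ≤ 8
observations and tie-free data, and otherwise uses the tie-corrected
normal approximation without continuity correction. Multi-group
continuous comparisons use one-way ANOVA. `anova_oneway()` also accepts
**summary statistics** (mean, SD, n per group) and reconstructs the sums
of squares algebraically — identical to raw-data ANOVA, which the tests
verify to 1e−10 — so published tables can be re-tested without raw data.
Quantiles everywhere use linear interpolation between order statistics
(R's default type 7), chosen once and documented because summary
conventions differ across software. Reported p-values are rounded to 3
decimals in output tables.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws a suppressed DTC group (default n = 64; 62.5%
male; age 48.86 ± 11.57 years truncated to [25, 85]; BMI 25.12 ± 3.82
kg/m² truncated to [16, 40]) and a euthyroid control group (n = 30; age
46.10 ± 14.17; BMI 25.96 ± 3.69). TSH is log-normal: median 0.22 µIU/mL
for cases with `sdlog = 2.4`, clipped to [0.001, 10]. The target median
and interquartile spread for a suppressed cohort cannot both be matched
exactly by any log-normal — the reported spread (≈ 0.02–1.07) is wider
below the median than a log-symmetric law allows while stratum counts
imply far fewer sub-0.1 values — so `sdlog = 2.4` is a documented
compromise (implied IQR ≈ 0.044–1.11) that also keeps sub-detection
values (< 0.008) uncommon. Controls use median 1.8, `sdlog = 0.35`,
clipped to the euthyroid [0.5, 4]; no description of the control
distribution was available, so this is our assumption. Risk-flag
prevalences default to the observed ones (prior fracture 10.9%, parental
hip fracture 4.7%, smoking 12.5%, RA 3.1%, secondary osteoporosis 9.4%,
alcohol ≥ 3 units/day 7.8%, glucocorticoids 0). Years since surgery are
exponential with mean 2.70, truncated at 15, absent for controls.

T-scores follow a linear model: intercept −0.33, **−0.04 per year of
age**, −0.35 for male sex, +0.05 per BMI unit, Gaussian residual SD 1.5,
and a **−0.27 shift for the disease group** — the mean T-score deficit
attributable to suppression therapy, read as an absolute shift. The
intercept was set so the control mean lands near −1.09 at the control
covariate means, which puts roughly a quarter of the disease group below
−2.5. The TSH→T-score coupling (`t_log_tsh_slope`) **defaults to zero**,
because in the population this emulates the T-score showed no gradient
across TSH strata; a positive value simulates the alternative hypothesis
in which suppression itself erodes bone.

What the generator does *not* emulate: longitudinal dosing history,
within-patient TSH variability, site-specific (femoral vs lumbar) BMD
differences — the model takes a single hip T-score and treats it as the
gold standard, although real cohorts measure both sites — comorbidity
structure (diabetes, hypertension), and any real covariance between risk
flags and TSH. Passing tests therefore demonstrate the *software's*
correctness and the *internal* coherence of the analysis, not clinical
validity on real patients.

`recover_parameters()` closes the loop: replicated cohorts are refit by
OLS and the recovered age slope and disease shift must land within a few
standard errors of the generating values.

## Simulation findings the test suite computes

Two qualitative orderings are evaluated over replicated default-design
cohorts (n = 64, disease group only, 200 seeds; the acceptance script
recomputes them for any seed):

* AUC of the BMD-informed score exceeds both BMD-free scores in
  **every** replicate — necessarily, since the gold standard is itself a
  T-score threshold and only the `with_bmd` score sees the T-score.
* Specificity at the Youden cutoff for the TSH-weighted score exceeds the
  unweighted score in only **~43–47%** of replicates. Under the default
  zero-coupling design the TSH penalty is independent noise with respect
  to the gold standard, so this comparison is structurally a coin flip,
  further tilted below one half by the heavy one-decimal ties and the
  sensitivity-favouring tie-break. Switching the coupling on
  (`t_log_tsh_slope` ≈ 0.15–0.3) raises the MOF fraction toward ~0.6 but
  not decisively. The corresponding acceptance expectation is therefore
  left failing by design rather than weakened: a single observed cohort
  can certainly show the specificity gain — individual seeds do, often
  dramatically — but it is not a majority property of this generator, and
  we report that honestly instead of tuning the generator until it is.

## Problem sizes and runtime choices

Test and acceptance problem sizes are chosen to make each check sharp but
cheap: 10⁶ random TSH levels for weight-table coverage, 1000 random
instances (≤ 30 subjects) for the AUC identity, 300 for the Youden
oracle, 100 replicates of n = 500 for parameter recovery, 200 replicates
of n = 64 for the ordering fractions, and n = 60 000 single draws for
marginal calibration. The full suite runs in well under a minute on one
CPU.

## Known limitations

* The surrogate's absolute probabilities are not FRAX's; only signs,
  orderings, and the interface are guaranteed.
* The weighting table is a step function with conservative boundary
  closure; a patient exactly at 0.1 µIU/mL gets +15, not +10.
* The effective-age cap at 90 compresses risk differences among elderly,
  deeply suppressed patients.
* Single-site T-score: the hip/lumbar ambiguity is resolved by fiat to a
  single `t_score` column.
* Exact Mann–Whitney enumeration is only used for small tie-free
  samples; elsewhere the normal approximation is standard but
  approximate.
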