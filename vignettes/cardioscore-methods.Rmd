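---
title: "Methods: risk stratification, competing-risks validation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk stratification, competing-risks validation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cardioscore` implements a harmonized, treatment-agnostic variant of the
HFA-ICOS baseline cardiovascular-toxicity risk proforma for cancer patients,
together with everything needed to validate such a rule-based score against
long-term cardiovascular outcomes under competing mortality. This vignette
is the package's account of the science: the scoring rules and the choices
behind them, the endpoint and estimator definitions, the imputation and
synthetic-data machinery, and the limits of what the test suite can show.

## The scoring model

The HFA-ICOS proforma assigns each baseline risk factor a weight — medium
(1 or 2 points), high, or very high — and maps the profile to one of four
categories:

* **VERY HIGH** — any very-high factor (heart failure or cardiomyopathy);
* **HIGH** — otherwise, any high factor *or* at least 5 medium points;
* **MODERATE** — otherwise, 2–4 medium points;
* **LOW** — 0–1 medium points.

The original proforma is treatment-specific (seven schemes, one per therapy
class). This package implements the harmonized variant used when a single
baseline assessment must cover a general oncology population: where schemes
disagree on a predictor's level, the most frequently assigned level is
used, and biomarker/imaging rows (troponin, NT-proBNP, LVEF) are omitted as
typically unavailable at scale. The factors and weights are:

| Factor | Weight |
|---|---|
| Heart failure / cardiomyopathy | very high |
| Coronary artery disease (MI, PCI/CABG, stable angina) | high |
| Arterial vascular disease (stroke/TIA, PAD) | high |
| Significant valvular disease | high (see below) |
| Prior anthracycline exposure | high |
| Age ≥ 80 y | high |
| Age 65–79 y | medium, 2 p |
| Arrhythmia (AF, flutter, VT) | medium, 2 p |
| Hypertension; diabetes; hyperlipidemia; CKD; current smoking; obesity; prior chest/mediastinal RT; prior non-anthracycline chemotherapy | medium, 1 p each |

Derived definitions (`derive_predictors()`): hypertension is
antihypertensive use **or** blood pressure above 140/90 mmHg; hyperlipidemia
is non-HDL cholesterol (total − HDL) above 3.8 mmol/L; CKD is eGFR below
60 mL/min/1.73 m² or a recorded diagnosis; obesity is BMI above 30 kg/m².
All thresholds are strict inequalities (a BMI of exactly 30 is not obese, a
BP of exactly 140/90 is not hypertensive), matching the proforma's printed
operators, and the age bands are [65, 80) and [80, ∞).

Three genuinely open design points, and how they were decided:

* **Blood-pressure rule.** "Above 140/90" does not say whether the systolic
  and diastolic components combine with OR or whether only the systolic
  matters. The default is disjunctive (systolic > 140 OR diastolic > 90),
  the conventional clinical reading; `scoring_config(bp_rule =
  "systolic_only")` gives the other reading.
* **Valvular disease.** It is not a row of the harmonized table, but
  category-stratified frequency tables from the external validation this
  package emulates show exactly 0% valvular disease in the low and moderate
  categories — only possible if valvular disease forces at least HIGH. The
  default therefore treats it as a high factor; `scoring_config(valvular_high
  = FALSE)` disables it.
* **Prior vs received therapy.** Only exposures *before* the baseline
  assessment (prior anthracycline, prior chest RT, prior other chemotherapy)
  feed the score. Therapies received after baseline define subgroups (e.g.
  anthracycline-treated) and never change the category.

Scoring is a total function on complete profiles: the property suite fuzzes
random profiles and checks exhaustiveness, monotonicity (adding a medium
factor never lowers the category; a high factor forces ≥ HIGH; heart
failure always VERY HIGH), and the structural zeros above. Missing data are
resolved *before* scoring (below); strict mode errors naming the subject
and field, complete-case mode drops incomplete rows with a warning.

## Endpoints

The primary outcome is the composite of first HF hospitalization (primary
discharge diagnosis), nonfatal stroke (primary), nonfatal MI (primary or
secondary), or cardiovascular death; non-cardiovascular death is the
competing event and administrative end of follow-up the censoring
mechanism. `build_outcome()` scans a subject's event stream and returns
`(time, status)` with status 0/1/2. Conventions: a qualifying event tied
with a death at the identical time resolves to the event ("first
occurrence" semantics — the ordering only matters at exact ties, which
continuous time makes measure-zero); an event at exactly the horizon
counts, censoring applies strictly after; follow-up starts at cancer
diagnosis with no delayed entry. Single-cause variants (HF-only, MI-only)
keep the diagnosis-position rules and treat *all* deaths as competing. The
follow-up horizon is a configuration value, not a constant, because
administrative censoring dates are study-specific; the synthetic generator
attaches per-subject censoring times (`followup_years`).

## Estimators and regressions

All estimators are implemented directly (the `survival` and `cmprsk`
packages appear only as independent cross-checks in the test suite):

* **Kaplan-Meier** with Greenwood variance and a plain normal pointwise
  interval clipped to [0, 1].
* **Nelson-Aalen** cumulative hazard, also used to carry the outcome into
  imputation models as H(T_i).
* **Aalen-Johansen** cumulative incidence functions; the implementation
  maintains S(t) + F₁(t) + F₂(t) = 1 at every step, and tests assert the
  classical inequality that 1 − KM overestimates a CIF under competing
  risks.
* **Harrell's C** of the ordinal category: a pair (i, j) is comparable when
  subject i has the event and t_i < t_j (time-tied event pairs are
  excluded); tied scores count one half. Competing deaths are passed as
  censorings — common practice when validating a baseline score against a
  composite, though it makes C a censoring-distribution-dependent quantity.
  The default CI is a normal approximation whose variance comes from
  per-subject pair-sum influence terms; a leave-one-out jackknife over the
  same sums is available (`ci_method = "jackknife"`).
* **Cox regression** by Newton-Raphson on the Breslow partial likelihood:
  gradient sup-norm tolerance 1e-8, at most 100 iterations, step halving
  when the objective decreases, SEs from the inverse observed information.
  Breslow tie handling is the simplest consistent choice at this data
  scale. Rank-deficient or constant covariate columns are rejected;
  coefficients diverging past |β| > 10 set a `separation` flag and mark the
  fit non-converged rather than failing silently.
* **Fine-Gray regression** for the subdistribution hazard: subjects failing
  from the competing cause stay in later risk sets with IPCW weights
  w_i(t) = G(t−)/G(T_i−), where G is the pooled (covariate-free)
  Kaplan-Meier estimate of the censoring distribution, as in the original
  formulation. The weighted risk-set sums decompose into a reverse
  cumulative sum over subjects still under observation plus G(t−) times a
  prefix sum over past competing failures, so each Newton step is
  O(n log n). With zero competing events the fit reduces *exactly* to the
  Cox fit (asserted in tests). SEs are model-based (inverse information);
  the robust sandwich variance of the original formulation is not
  implemented, a known limitation that affects CIs, not point estimates.

Classification metrics dichotomize the tool (positive = HIGH/VERY HIGH,
condition = composite event over full follow-up) and report both raw
proportions and integer percentages rounded half away from zero; empty
denominators yield `NA` markers. Crude incidence is the plain proportion of
subjects with status 1 — deliberately unadjusted for censoring, because the
reported per-category incidences of the validation study multiply back to
its total event count, identifying them as crude proportions; the
Aalen-Johansen curves are the competing-risk-adjusted complement.

## Imputation

`mice_impute()` is a minimal chained-equations imputer mirroring the
classical MICE configuration: m = 5 completed datasets, 5 sweeps each,
predictive mean matching for numeric columns (donor pool k = 5, the
standard default), logistic regression for binary columns, polytomous
regression (`nnet::multinom`) for factors. Columns are visited in ascending
missingness (a common convention; nothing here depends on it), models are
fit on originally observed rows against the current working data, and the
censored outcome enters every model as the Nelson-Aalen cumulative hazard
at the subject's own time plus the event indicator. Observed cells are
never altered; runs are bit-reproducible given the seed; per-iteration
imputed-cell means are returned for visual convergence checks. The default
analysis selects a *single* completed dataset uniformly at random —
matching how rule-based scores are validated in practice, where a single
analysis table is stratified — with Rubin pooling (`pool_estimates()`)
available as a reporting mode. Descriptions of such analyses sometimes
mention imputing "a random sample" of the table; we read that as a tooling
artifact and always impute the full table.

## The synthetic cohort generator

No subject-level data from the emulating study's registries can be
shipped, so the generator builds cohorts with the statistical structure the
analysis assumes, calibrated to that study's reported margins. Its defaults
*are* the study conditions and are not tuning knobs:

* n = 2,290; category mix 28/35/34/3% (LOW/MODERATE/HIGH/VERY HIGH);
* per-category predictor prevalences from the category-stratified baseline
  table (diabetes 1/6/15/24%, coronary disease 0/0/43/65%, heart failure
  0/0/0/100%, and so on), cancer-type mix and post-baseline treatment
  probabilities likewise;
* composite-CVD cumulative incidence 7/21/29/37% anchored at 6.9 years and
  all-cause mortality 32/55/79/89% anchored at 8.7 years (the pooled median
  follow-up times of the respective analyses);
* administrative censoring Uniform(11, 17) years, reflecting diagnosis over
  2006–2012 with follow-up through 2023;
* first-event cause split 87/161/130/82 out of 460 (HF hospitalization /
  MI / stroke / CVD death), MIs randomly primary or secondary.

**Construction is category-first.** The intended category is drawn from the
mix, predictors from that category's conditional prevalences, and the draw
is then *minimally repaired* so the scoring engine maps the subject exactly
to the intended category: heart failure forced on (only) for VERY HIGH,
high factors stripped below HIGH, ages resampled into admissible bands, and
medium points brought into range by adding or removing single factors
(2-point factors only removed when the excess allows). Every field change
is counted in the returned `repair_log`, so the prevalence distortion the
repair introduces is measurable — on default cohorts it touches a minority
of subjects, concentrated in smoking/obesity/lipid fields of LOW subjects.
Scoring consistency is exact by construction and asserted in tests.

**Event times are competing exponentials.** Each category gets latent
T_cvd ~ Exp(λ_cvd) and T_death ~ Exp(λ_death); the validated analyses fit
no event-time model, and exponentials give closed-form cumulative
incidences for calibration. Two calibration routines exist because the two
targets have different semantics:

* `calibrate_exponential_hazards()` — both targets are competing-risk CIFs
  at a single horizon; closed form, with the infeasibility guard
  p₁ + p₂ < 1.
* `calibrate_marginal_hazards()` — what `generate_cohort()` uses. The
  mortality targets above are *all-cause* figures: they include subjects
  who died after a nonfatal CVD event, and for the upper categories they
  exceed 1 when summed with the CVD CIF (29 + 79%, 37 + 89%), so they
  cannot be competing-death CIFs. The routine therefore solves, by nested
  bisection to 1e-10,
  (λ_c/Λ)(1 − e^(−Λh₁)) = p_cvd and
  (1 − e^(−λ_d h₂)) + q·e^(−λ_d h₂)(1 − e^(−λ_c h₂)) = p_death,
  with q the fatal share of first CVD events (82/460): death by t occurs if
  the latent death time has passed, or if a fatal first CVD event has. A
  Monte-Carlo round trip at n = 10⁵ confirms both targets.

Quantities the generator does **not** attempt to match: per-category median
follow-up (not reported per category; all categories share the pooled
anchors, an approximation), diastolic blood pressure (not reported by
category; drawn N(78, 10²) independent of category — it only feeds the
disjunctive hypertension rule), prior-exposure prevalences (prior
anthracycline/chest-RT/chemotherapy before baseline are not in the reported
baseline table; small realistic defaults of 0–6% were chosen once, with
prior anthracycline structurally zero below HIGH), and any correlation
structure between predictors beyond what the category conditioning
induces. Sex-specific cancers override the drawn sex (prostate → male,
female genital → female, breast → 99% female). Default missingness is 0 —
the generator emulates the *post-imputation* analysis table; MCAR
missingness at a configurable per-predictor rate (the validated analyses
faced 1–4%) is opt-in for exercising the imputation module.

What passing tests on this cohort do and do not show: they demonstrate that
the pipeline — scoring, endpoint construction, estimators, regressions —
recovers the configured structure at realistic scale, and that a cohort
carrying the reported margins yields a Harrell C close to the reported
0.696 (the acceptance analogue averages C over 20 seeds and lands near
0.686 ± 0.013). They do not validate the proforma on real patients: real
cohorts have correlated predictors, non-exponential hazards,
treatment-dependent censoring and coding noise, none of which the generator
models.

## Pipeline, numerical conventions, and problem sizes

`run_validation()` orchestrates impute → score → outcomes → estimate →
report. Imputation precedes scoring; a single completed dataset is the
analysis input. Sensitivity switches mirror the validated analyses:
metastatic exclusion; a 2-year landmark implemented as removing subjects
whose outcome time is below 2 years; treatment subgroups (anthracycline,
pooled cardiotoxic therapy) with HIGH and VERY HIGH merged, as done when
subgroup sizes are small. Category hazard ratios versus LOW are emitted
from *both* Cox and Fine-Gray fits, since validation reports often leave
the model unstated; per-predictor subdistribution HRs come unadjusted and
age/sex-adjusted. Reports carry raw floats alongside paper-style rounded
integers (half away from zero), and identical configurations produce
byte-identical reports.

Test-suite problem sizes (the package's own choices, balancing Monte-Carlo
error against runtime): 20 seeds × n = 2,290 for the discrimination check;
50 replicates at n = 2,000 for Cox/Fine-Gray parameter recovery (true
log-HR 0.5, |bias| < 0.05); n = 10⁵ for calibration round trips; 100 random
datasets for exact brute-force concordance equality; 200–300 random
profiles for scoring fuzz. The full suite runs in about 80 seconds.

## Known limitations

* Fine-Gray SEs are model-based, not robust; CIs for sHRs are accordingly
  approximate.
* Harrell's C under competing risks treats competing deaths as censorings;
  a cause-specific or IPCW concordance would differ.
* The generator's exponential hazards cannot express the early mortality
  spike real oncology cohorts show in year one.
* Calibration accuracy of the proforma itself cannot be assessed — it has
  no published risk equation — so discrimination is the only validated
  dimension, here as in the emulating study.
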