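---
title: "Validating SCORE2 in routine-care cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating SCORE2 in routine-care cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package does

SCORE2 is the European 10-year cardiovascular (CVD) risk equation: a
sex-specific Fine–Gray model on age, smoking, systolic blood pressure and
cholesterol, recalibrated to four European risk regions (low, moderate,
high, very high). National guidelines pick one region model per country;
subgroups within a country may nonetheless carry systematically different
baseline risk. `score2val` packages everything needed to *externally
validate* the four region models in a routine-care cohort with competing
risks, substantial missingness, and socioeconomic/ethnic subgroups — and,
because registry cohorts of this kind cannot be shared, a synthetic cohort
generator that emulates their statistical structure so the entire pipeline
is testable end to end.

## The risk engine

For a profile with age $a$, smoking $s$, systolic blood pressure $b$,
total cholesterol $c$ and HDL cholesterol $h$, each term is centred and
scaled (for example $\tilde a = (a-60)/5$, $\tilde b = (b-120)/20$) and the
linear predictor is the inner product with the published sex-specific
log-subdistribution-hazard coefficients, including the four age-interaction
products. The uncalibrated 10-year risk is

$$r = 1 - S_0(10)^{\exp(\mathrm{lp})},$$

and the region-recalibrated risk applies the published scale pair
$(s_1, s_2)$ on the complementary log-log scale:

$$r^\ast = 1 - \exp\!\big(-\exp\big(s_1 + s_2 \log(-\log(1-r))\big)\big).$$

With $s_1=0, s_2=1$ this is the identity; $s_2>0$ preserves ranking, so the
four region models share discrimination and differ only in calibration.
One practical subtlety of the published scale pairs: the region lines cross
at very low risk (the moderate- and high-region lines meet near 3%
uncalibrated risk in men and 0.5% in women), so "higher-risk region ⇒
higher predicted risk" holds in the clinically relevant range but not
globally. Nothing in the validation machinery relies on global ordering.

All numeric content — coefficients, $S_0(10)$, the eight scale pairs, the
centring/scaling constants — lives in a versioned JSON configuration
(`inst/extdata/score2_coefficients.json`), transcribed from the published
SCORE2 supplementary material. The engine never hard-codes them, so a
corrected or re-derived coefficient set is a data change, not a code
change. The term schema also admits a single non-HDL-cholesterol term
(value $c-h$) instead of separate total/HDL terms: validation reports for
this model family sometimes describe the predictor set either way, and both
parameterisations load without code changes. The default configuration uses
separate total and HDL terms, matching the published model.

Treatment categorisation uses the ESC age-specific thresholds — 2.5%/7.5%
under age 50, 5%/10% at 50–69 — with half-open intervals and the upper
boundary inclusive upward (risk exactly at a threshold falls in the higher
category, the conventional "at or above threshold, treat" reading). Age for
threshold selection is age at prediction, i.e. cohort entry.

## Cohort data model

The person-level schema carries registration dates, measurement values with
dates and source (GP preferred over hospital), ICPC-coded first CVD events,
ICD-10-coded deaths, income quintile (1 = lowest) and ethnicity
(dutch / surinamese / other, finer origin labels passed through).

* **Entry** is the latest of registration start, the study start
  (2007-01-01) and the 40th birthday; persons whose entry would fall at or
  after their 70th birthday, their registration end, or the administrative
  end of study (2020-07-01) never enter.
* **Exclusions**: prior CVD, diabetes, statin or diabetes-medication use
  before entry, and registration spans under six months. Every dropped
  record carries one machine-readable reason, so kept + dropped always
  reconciles with the input (flowchart conservation). Missing binary
  history flags are read as "absent".
* **Follow-up** ends at the first of: qualifying CVD event or CVD death
  (the combined endpoint), non-CVD death (the competing event), the 80th
  birthday, deregistration, or the administrative end. A CVD event and a
  death on the same date count once, as a CVD event. Person-years use a
  365.25-day year. Same-day terminal events are given half a day so times
  stay positive.
* **Baseline measurements** take, per variable, the GP source first; within
  a source the latest value at or before entry, else the earliest value
  after entry within a bounded look-ahead window (default 365 days — the
  report this design follows gives no window, and an unbounded look-ahead
  would let late follow-up values masquerade as baseline).
* **Smoking** missing is assumed non-smoking, mirroring how such GP data
  are analysed.

## Imputation

Blood pressure, total and HDL cholesterol and the income quintile are
imputed by chained equations with predictive mean matching (continuous
variables; the quintile is matched on the numeric 1–5 scale so imputed
values are always observed quintiles). Default predictors: age, sex,
smoking, the other incomplete variables, the auxiliary correlates fasting
glucose and eGFR, ethnicity, follow-up time and the CVD event indicator.
Sex is included even though validation reports of this family usually list
the predictors without it: the lab distributions are strongly sex-specific,
and a pooled imputation model without sex measurably shifts the mean
predicted risk of each sex in opposite directions.

Defaults are $m=5$ completed datasets and 10 sweeps; convergence is
assessed on per-variable chain means/SDs (run with `maxit = 40` for a
convergence check; `imputation_convergence()` flags trending chains).
Performance estimates are pooled with Rubin's rules,
$T = W + (1+1/m)B$: observed/expected ratios on the log scale
(back-transformed), Harrell's C on the identity scale with its analytic
variance, intervals by normal approximation on the pooling scale.

## Validation metrics under competing risks

* **Observed risk** at the 10-year horizon is the Aalen–Johansen cumulative
  incidence of the CVD event with non-CVD death competing, computed through
  the multi-state machinery of `survival`. Treating the competing event as
  censoring (1 − Kaplan–Meier) would overstate observed risk; the
  Aalen–Johansen choice matches the Fine–Gray predictions being validated.
* **OE-ratio** = observed cumulative incidence / mean predicted
  probability; above 1 means underprediction. The interval uses the delta
  method on $\log \mathrm{OE}$ with the expected value treated as fixed,
  $\exp(\log\mathrm{OE} \pm z\,\sqrt{\widehat{\mathrm{var}}(O)}/O)$.
  Published intervals for this quantity are sometimes implausibly tight
  and rarely state their construction, so intervals here are a stated
  convention, not a reproduction target.
* **Calibration curves** bin the sample into deciles of predicted risk
  (stable ordering so ties keep input order), compute the per-bin
  Aalen–Johansen incidence with a normal interval, and overlay a LOESS
  smooth (span 0.75, degree 1) fitted over a finer grid of quantile bins
  weighted by bin size — individual-level smoothing of a censored
  competing-risk outcome would otherwise require pseudo-observations,
  which are quadratic-cost at registry scale.
* **Harrell's C** treats competing deaths as censoring at the death time
  (the classic definition) and truncates follow-up at the 10-year horizon
  for consistency with fixed-horizon predictions (toggle
  `truncate_at = Inf` for full follow-up; in the synthetic cohorts the two
  differ by well under 0.01). Computation is the $O(n \log n)$
  `survival::concordance`, with prediction ties counting one half.
* **Minimum-events gate**: strata with fewer than 200 observed events are
  reported but flagged non-evaluable, the usual external-validation
  sample-size floor.

`score2_validate()` orchestrates: build cohort, impute, predict per region,
stratify (sex, sex × ethnicity, sex × income quintile, optionally crossed),
gate, pool. `select_best_region()` picks, per stratum, the region whose
pooled OE is nearest 1 on the log scale, breaking ties toward the
lower-risk region (the conservative choice). `eligibility_shift()`
quantifies how region reassignment moves the share of individuals at or
above the upper treatment threshold; the upper threshold is the default
because "meeting treatment thresholds" in guideline language refers to the
drug-treatment cut-off (flag `use_upper = FALSE` for the lower one).

## The synthetic cohort generator

The generator emulates the structure the analysis assumes, calibrated to
the published baseline table of a Dutch urban primary-care cohort
(155,013 persons, 74,880 men):

* sex-specific ethnicity and income-quintile composition, and covariate
  marginals (age 48.1 ± 8.6 / 48.3 ± 8.8; SBP 138 ± 21 / 134 ± 22;
  total cholesterol 5.5 ± 1.1; HDL 1.2 ± 0.3 / 1.5 ± 0.4; smoking
  33.4% / 32.1% for men / women);
* **ages** come from a moment-matched scaled Beta on [40, 70). A truncated
  normal cannot reach the printed spread at the printed mean (its maximal
  sd there is about 7.3 years), and the age spread drives discrimination,
  so fidelity to both printed moments wins over the distribution family;
  the solved shape is J-shaped, which is what a dynamic cohort with steady
  inflow of newly eligible 40-year-olds looks like;
* covariates are drawn independently within sex except a configurable
  age–SBP correlation (default 0.3); only marginals are published;
* **smoking**: the printed prevalence is the post-assumption analysis
  prevalence (half the records lack a smoking entry and are assumed
  non-smoking), so the generator draws the analysis-level value at the
  printed rate and assigns the "missing" source flags among the
  non-records. Masking recorded smokers to non-smoker instead would
  contradict the printed marginal and shift expected risk by several
  percent;
* **designed truth**: each person's true 10-year CVD probability is a
  stratum multiplier times their low-region SCORE2 prediction (capped at
  0.95), computed on pre-masking lab values and the analysis-level smoking
  value. This encodes subgroup observed/expected structure as a recoverable
  design parameter; the real risk-generating process is of course richer;
* **event times**: the true CVD probability and a per-sex competing
  non-CVD-death probability (defaults 0.033 / 0.027 at 10 years, a
  documented one-time calibration to the published observed event shares)
  are inverted jointly to constant cause-specific hazards — closed form,
  $\Lambda = -\log(1-p_1-p_2)/h$, $\lambda_1 = \Lambda p_1/(p_1+p_2)$ —
  and latent times drawn accordingly, with hazards continuing beyond the
  horizon;
* **censoring**: 55% of persons are prevalent at the study start, the rest
  register uniformly over the following 12 years; deregistration is
  exponential at 0.025/year. This one-dimensional calibration reproduces
  the published median follow-up (9.9 years) to within a few weeks; the
  interquartile range is somewhat wider at the top than the published
  5.7–12.8 because administrative censoring concentrates prevalent
  entrants at the maximal 13.5 years;
* **missingness**: labs and income quintile are masked missing-at-random
  through a logistic model in age and income, with intercepts calibrated by
  root-finding to the printed marginal rates (31/35/36/6%); the outcome
  proxy (statin + antithrombotic start) flags CVD cases at sensitivity
  0.93;
* **variance reduction**: the latent uniforms behind event times, the
  cause split, the entry mixture and deregistration are stratified
  (randomly permuted, jittered systematic grids) within
  sex × ethnicity × income cells. Every person's marginal draw is exactly
  uniform, so all marginal and calibration properties are untouched, but
  cell-level event counts concentrate on their expectation: designed
  subgroup quantities are recovered with far less Monte-Carlo noise at a
  given cohort size. A side effect of the induced negative dependence is
  that the analytic Aalen–Johansen variance slightly overstates the
  generator's true sampling noise, making confidence-interval coverage of
  designed values conservative;
* a truth table (designed probabilities, hazards, latent times, pre-masking
  values) is emitted alongside for oracle checks and is never consumed by
  the pipeline.

One estimator choice deserves a note: income-quintile strata can be formed
from observed-plus-imputed membership (mirroring studies that impute
income) or from observed membership only. In the generator, income is
independent of every imputation predictor, so imputed membership is
near-random and dilutes a designed subgroup effect toward the population
mean (about −0.02 on an OE of 1.6); real income data are partially
recoverable from correlates, so real studies sit in between. The shipped
recovery checks therefore stratify on observed income, while
`impute_ses = TRUE` (the default elsewhere) and `sensitivity_suite()`
exercise both modes.

Four presets: `table1_default` (sex-level multipliers 1.30 / 1.22, the
published overall calibration gap), `ethnicity_multipliers` (Dutch
1.21 / 1.15, Surinamese 1.92 / 1.86, other 1.40 / 1.20 by sex),
`ses_multipliers` (income-quintile multipliers log-linearly interpolated
between the published extreme quintiles, 1.54→1.17 men, 1.64→0.94 women —
only the extremes are published), and `null_calibration` (multiplier 1, no
missingness, isolating the estimator).

What passing recovery tests does and does not show: the generator draws
covariates independently within cells, gives every ethnicity the same
covariate distribution, has no measurement error, no secular trends, no
household clustering, and its true risk is exactly proportional to the
model prediction within stratum. Recovery therefore certifies the
*pipeline* (data handling, imputation, estimators, pooling), not the
clinical accuracy of SCORE2 in any real population.

## Numerical and degenerate-input conventions

Recalibration rejects risks exactly 0 or 1 (the cloglog transform is
undefined there) and non-positive $s_2$. Prediction requires complete
profiles — imputation happens upstream — and errors on non-finite linear
predictors. Constant predictions collapse calibration bins to one with a
warning and give C = 0.5 by the tie convention. Empty strata are skipped;
strata whose events fall below the gate are reported unflagged rather than
dropped. Imputation refuses variables that are entirely missing and
missingness outside its configured scope. The two-cause inversion rejects
incidence pairs summing to 1 or more. All generators and the full
validation run are deterministic given their integer seed.

## Problem sizes used by the shipped tests

Unit and property tests run on cohorts of a few hundred to 60,000 persons.
The designed-truth recovery tests in the acceptance suite generate the full
155,013-person scenarios with $m=5$ imputations (about 1–2 minutes each),
and the null-calibration coverage check uses twenty replicates of 20,000
persons. These sizes were chosen so the complete suite exercises
registry-scale code paths while remaining comfortable to run on a laptop.

## Known limitations

* Coefficients are transcribed published values; the package validates, it
  does not re-derive, SCORE2.
* The OE interval treats the expected value as fixed; with region
  reassignment or refitting it would be optimistic.
* The LOESS overlay smooths bin-level, not individual-level, observations.
* Subgroup OE recovery at registry scale carries sampling noise of roughly
  ±0.1 for a 4,000-person stratum; single-seed subgroup checks should be
  read with that in mind.
* Deciles use stable ordering rather than randomised tie-breaks, so heavily
  tied predictions give slightly unequal bins.
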