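---
title: "Marginal structural Cox models for time-varying anemia in early CKD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal structural Cox models for time-varying anemia in early CKD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Anemia in chronic kidney disease is often transient: hemoglobin can fall as
renal function declines and recover with treatment. Estimating the causal
effect of *current* anemia status on renal progression, cardiovascular
events and death is therefore a time-varying-exposure problem with
time-dependent confounding: eGFR and anemia treatment predict future anemia
and future outcomes, and are themselves affected by past anemia. Standard
regression adjustment for such covariates is biased — adjusting blocks part
of the exposure's pathway and conditions on variables affected by earlier
exposure — which is the textbook indication for marginal structural models
(MSMs) fitted by inverse probability of treatment weighting.

`anemiaMSM` implements the full analysis pipeline for this setting:

1. **Cohort construction** from annual health-checkup records linked to
   medical/pharmacy claims and enrollment data. A subject enters at the
   *index date*: the second member of the first consecutive eGFR pair, at
   most two years apart, in which a value $\ge 60$ mL/min/1.73 m² is
   followed by a value $< 60$ (eGFR from the three-variable Japanese
   equation $194 \cdot \mathrm{SCr}^{-1.094}\cdot \mathrm{age}^{-0.287}$,
   $\times 0.739$ for females). Eligibility requires a 1-year lookback,
   2 years of follow-up unless deceased, and hemoglobin plus dipstick
   proteinuria at index; exclusions cover a first-ever eGFR already below
   60, prior dialysis or transplantation, eGFR < 6, and the absence of any
   post-index eGFR within 38 months.
2. **Exposure**: anemia by the age–sex specific hemoglobin cutoffs
   (male 13.5 / 12.0 / 11.0 g/dL and female 11.5 / 10.5 / 10.5 g/dL for
   ages < 60, 60–69, ≥ 70; strictly below the cutoff), re-evaluated at every
   annual checkup.
3. **Outcomes**: a composite renal endpoint (first of a ≥ 30% eGFR decline
   within 3 years of index, serum-creatinine doubling, chronic dialysis,
   kidney transplantation, or eGFR < 15), a composite cardiovascular
   endpoint (first claim for unstable angina, myocardial infarction, heart
   failure or a cerebrovascular event, fatal or not), and all-cause death.
4. **Stabilized weights, MSM fitting, and the sensitivity battery**
   (weight truncation, Fine–Gray competing risks, hemoglobin-quintile
   exposure, propensity-score matching, eGFR slopes).

# The stabilized weight model

The analysis unit is the person-period: one row per subject per annual
checkup interval, indexed $k = 0, 1, \dots$ with $k=0$ at the index
checkup. For subject $i$ in period $k$ the stabilized weight is the
cumulative product

$$ SW_{ik} \;=\; \prod_{j=0}^{k}
   \frac{P(A_j = a_{j,i} \mid \bar A_{j-1} = \bar a_{j-1,i})}
        {P(A_j = a_{j,i} \mid \bar A_{j-1} = \bar a_{j-1,i},
           \bar C_j = \bar c_{j,i})}, $$

with $\bar A_{-1} \equiv 0$. Both probabilities come from pooled logistic
regressions over periods $k \ge 1$; at $k = 0$ the special case applies and
baseline covariates alone are used (an intercept-only numerator and a
logistic denominator on the baseline covariate set). Design choices:

* **Exposure history** enters as the single lag $A_{k-1}$ by default; a
  `cumulative_history` flag adds the running count of exposed periods.
* **Time intercept**: a restricted cubic spline with five knots in
  Harrell's parameterization — the linear time term plus three normalized
  truncated-cube regressors that vanish below the first knot and are linear
  beyond the last. Knots sit at the (0.05, 0.275, 0.50, 0.725, 0.95)
  quantiles of observed period-start times.
* **Numerator covariates**: exposure history and the spline time intercept
  only, the literal reading of the product formula; a
  `numerator_baseline` flag adds baseline covariates (common practice).
* **Denominator covariates**: the time-varying set at $k-1$ and $k$
  (eGFR, treatment, proteinuria, HbA1c, smoking, comorbidity score — the
  set is configurable) plus the baseline covariates.
* **Fitting**: ordinary maximum-likelihood logistic (or multinomial, for
  the hemoglobin-quintile variant) fits. Apparent separation is an error
  with a diagnostic message, never silently regularized.
* **No censoring weights** are used. Disenrollment is treated as
  non-informative, matching the primary analysis this package mirrors; the
  synthetic-data generator (below) keeps its mortality process independent
  of the shared susceptibility so that this simplification is exactly
  correct in the test bed.

The MSM itself is a weighted Cox partial likelihood (Breslow ties,
consistent with the Breslow baseline-hazard estimator; Efron available)
with the time-updated exposure as the only design term, on (start, stop]
person-period intervals with event/censoring times kept in days inside the
final period. Variance is the cluster-robust sandwich by subject, which
accounts for the weighting-induced within-subject correlation (and is
conservative with respect to weight estimation). Counterfactual survival
under the "always anemic" and "never anemic" regimes is
$S(t \mid a) = \exp\{-\hat\Lambda_0(t)\, e^{\hat\beta a}\}$ with
$\hat\Lambda_0$ the weighted Breslow cumulative baseline hazard; interval
estimates use a subject-level nonparametric bootstrap (weights and Cox
refitted per replicate, percentile method, default 200 replicates) since no
closed-form interval is defined for this compound estimator.

# The synthetic cohort generator

No public data exist for this design, so the package ships a generator
whose causal structure is known exactly, and every downstream stage is
tested against it. The construction follows the standard device for
simulating data in which a marginal structural Cox model holds exactly:

* Each subject carries a latent susceptibility $z \sim N(0,1)$.
* Observed eGFR is $57 - 4z$ plus an annual drift of $-1.0$
  mL/min/1.73 m²/year, an extra $-0.75$ per prior anemic year, and
  measurement noise (SD 1.5).
* Anemia at period $k$ follows a logistic model on eGFR at $k-1$, anemia at
  $k-1$ and anemia treatment at $k-1$; treatment at $k$ follows a logistic
  model on anemia at $k-1$. Prior exposure therefore changes future
  confounders — genuine time-dependent confounding, switched off by
  `confounding_strength = 0`.
* For each outcome the subject draws a uniform $U$ whose probit loads on
  $z$ with correlation 0.85 (renal, cardiovascular) or 0 (death), and the
  event occurs when the cumulative hazard
  $\int h_0 e^{\beta A(t)}\,dt$ crosses $-\log U$. Because $U$ is uniform
  and independent of the exposure *regime*, the counterfactual survival
  function is exactly $\exp\{-\int h_0 e^{\beta a(t)}dt\}$: the marginal
  structural Cox model holds with the configured log hazard ratio on
  current exposure, with no non-collapsibility error. Since exposure
  depends only on *observed* history, sequential exchangeability holds
  given that history, so correctly specified weights identify $\beta$.
* A latent renal event manifests observably: from the next checkup on,
  eGFR drops to ≤ 65% of the index value and keeps declining, so the
  derived 30%-decline component fires; end-stage values additionally emit
  chronic-dialysis claims. Hemoglobin is drawn on the correct side of the
  age–sex cutoff so that re-classifying anemia from the emitted checkups
  reproduces the latent exposure sequence exactly, and serum creatinine is
  the exact inverse of the eGFR equation.

Under this construction the covariate-adjusted ("naive") time-dependent Cox
is biased upward — with lagged eGFR in the model the remaining bias channel
is frailty-driven survivor selection, and at the default settings it is
decisive (measured mean log-HR ≈ 0.80 against a truth of
$\ln 2 \approx 0.69$ at n = 4000, versus ≈ 0.71 for the MSM and ≈ 1.60
crude) — while the weighted analysis recovers the truth. This contrast is
the package's central correctness benchmark.

**Default study conditions.** Defaults were fixed once, before the test
suite was frozen, and are not tuned: true hazard ratios 2.56 / 1.63 / 2.76
(renal / cardiovascular / death — the published MSM point estimates for
this design); six annual post-index checkups; anemia prevalence 15% at
entry for a subject at the cohort-median eGFR (between the 4.2% of the
healthy-worker source population and the ~26% reported for established
stage-3 CKD; the healthy-worker rate would leave a recovery benchmark with
almost no exposed person-time); annual baseline hazards 0.02 / 0.03 / 0.008
(higher than the source cohort's very low event rates, again so that
Monte-Carlo benchmarks are informative at desk scale); annual disenrollment
10% (mean follow-up ≈ 4 years); 5% missingness, completely at random, in
non-key checkup fields.

**What the generator does not emulate.** Real claims have coding breadth,
visit-driven (informative) measurement times, non-random missingness, and
measurement error in creatinine; the generator has none of these. Passing
tests therefore demonstrate that the *estimators are correct under their
assumptions*, not that those assumptions hold in any particular claims
database.

# Sensitivity analyses

* **Weight truncation** winsorizes at the empirical 1st/99th percentiles
  (linear-interpolation percentile definition); order-preserving, contracts
  the weight spread.
* **Fine–Gray**: death treated as a competing risk for the renal outcome,
  via inverse-probability-of-censoring expansion of the data and a weighted
  Cox fit on the sub-distribution risk sets (expansion weights multiplied
  by analysis weights). With zero competing events this reduces exactly to
  the cause-specific fit.
* **Hemoglobin quintiles**: sex-specific empirical quintiles of baseline
  hemoglobin as a five-level exposure, weights from pooled multinomial
  models; the fifth (highest) category is the reference.
* **Propensity-score matching**: greedy 1:1 nearest neighbor on the logit
  propensity score, exposed subjects processed in descending propensity
  order with ties broken by subject id. "0.25 caliper" is read as 0.25
  standard deviations of the logit propensity score (the Rosenbaum–Rubin
  convention); a raw-logit caliper is available behind a flag since the
  published description admits either reading.
* **eGFR slopes** by per-subject ordinary least squares of eGFR on years,
  with the stage-3 restricted variant (first two post-index eGFRs < 60).
  The companion mapping from a slope difference to a percent hazard change
  anchors a 0.75 mL/min/1.73 m²/year slope benefit to a 27% lower hazard
  and scales proportionally on the log-hazard scale:
  $100\{(1/0.73)^{-\Delta/0.75} - 1\}$, so $\Delta = -0.7$ gives +34%.

# Numerical and procedural choices

* **Dates** are whole days; "within 2 years" is 730 days, "38 months" is
  1156 days (30.43 days/month), "3 years" is 1096 days — all exposed in
  configuration.
* **Exclusion precedence** is fixed (first failing rule counts a subject
  exactly once, in the order listed in `build_cohort()`), making the
  exclusion tally reproducible; the source description states no order.
* **Missing covariates**: baseline continuous → cohort median, baseline
  categorical → cohort mode, time-varying → last observation carried
  forward (from baseline) with cohort fallback; every imputed cell is
  logged. Key fields (index eGFR, baseline hemoglobin, baseline
  proteinuria) must be present — eligibility already guarantees this.
* **Degenerate inputs**: non-positive predicted exposure probabilities,
  empty quintile cells, zero-spread regression times, non-overlapping
  propensity distributions and fully missing columns raise immediate,
  specific errors; bootstrap replicates with zero events are redrawn.
* **Ties**: Breslow throughout by default; event times inside periods are
  continuous in the generator, so ties are a measure-zero concern there.
* The pooled logistic time basis is fitted on period *start* days; with
  annual checkups these take a handful of distinct values and the five-knot
  basis is exactly saturated rather than over-parameterized.

# Problem sizes used in the shipped checks

Monte-Carlo checks run at sizes chosen to make their tolerances
meaningful at desk scale: the parameter-recovery benchmark uses 200
replicates of n = 5000 subjects (mean MSM log-HR within 0.05 of $\ln 2$,
95% CI coverage in [0.90, 0.98], naive estimate outside the MSM tolerance);
weight stabilization and balance use single cohorts of n = 5000–6000;
Breslow/Kaplan–Meier agreement uses n = 2000 under the null; the weighted
Cox estimator is checked against a brute-force partial-likelihood optimizer
on ≤ 20-subject fixtures at 1e-8. The end-to-end pipeline demonstration
uses n = 400–500 subjects.

# Known limitations

* The robust sandwich interval ignores weight estimation and is therefore
  mildly conservative; the bootstrap bands for regime curves are the
  package's only weight-estimation-aware intervals.
* The default ICD-10 code map is an illustrative subset (Quan Charlson
  categories plus minimal cardiovascular event lists); real analyses must
  supply the study's validated code lists.
* No censoring weights, left truncation, recurrent events or frailty
  terms; doubly robust and targeted estimators are out of scope.
* Published adjusted hazard ratios and survival probabilities from the
  proprietary source cohort are structural references only — they are not
  reproducible without that data, and the package does not attempt to
  match them numerically.
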