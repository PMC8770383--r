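# anemiaMSM

Marginal structural Cox models for the causal effect of **time-varying
anemia status** on renal, cardiovascular and mortality outcomes in subjects
at the very beginning of impaired renal function (first eGFR
< 60 mL/min/1.73 m²).

Anemia in early chronic kidney disease is transient: hemoglobin falls as
eGFR declines and recovers under treatment. eGFR and anemia treatment are
*time-dependent confounders* — they predict future anemia and future
outcomes and are themselves affected by past anemia — so ordinary
covariate-adjusted regression is biased. The package implements the
standard remedy: person-period data with stabilized inverse probability of
treatment weights

```
SW_ik = prod_{j=0..k}  P(A_j = a_ij | A-history)
                      ---------------------------------
                       P(A_j = a_ij | A-history, C-history)
```

estimated by pooled logistic regressions with a five-knot restricted cubic
spline time intercept (baseline covariates alone at period 0), followed by
a weighted Cox fit of the time-updated exposure with a cluster-robust
sandwich variance, Breslow counterfactual survival curves
`S(t|a) = exp(-Λ0(t) e^{βa})` for the always/never-anemic regimes, and the
accompanying sensitivity battery: 1st/99th-percentile weight truncation,
Fine–Gray competing-risk fits for the renal endpoint, a sex-specific
hemoglobin-quintile multinomial-weight MSM, greedy caliper propensity-score
matching, and per-subject eGFR slopes with their slope-to-hazard
translation.

Upstream of the models, the package builds the analysis cohort from three
delimited tables (annual checkups, claims, enrollment): the index-date rule
(first consecutive eGFR pair ≥ 60 → < 60 within two years), the full
inclusion/exclusion battery with a reproducible exclusion tally, Quan
ICD-10 Charlson scoring, cardiovascular-history and baseline-diabetes
sub-cohort flags, age–sex hemoglobin anemia criteria, and the composite
renal/cardiovascular/death endpoints.

Because the motivating data are proprietary, the package ships a
**synthetic longitudinal cohort generator with known causal structure**:
the marginal structural Cox model holds exactly with the configured hazard
ratios, observed eGFR is a genuine time-dependent confounder, and the
covariate-adjusted "naive" Cox is decisively biased while the MSM recovers
the truth. Every stage of the pipeline is tested against it. See
`vignettes/methods.Rmd` for the model, the generator construction and all
design decisions.

## Worked example

```r
library(anemiaMSM)

## a 6,000-subject cohort with true renal HR 2, genuine confounding
cfg <- sim_config(n_subjects = 6000, seed = 42,
                  true_log_hr = c(renal = log(2), cv = log(1.63),
                                  death = log(2.76)))
sim <- simulate_cohort(cfg)

## person-periods -> stabilized weights -> marginal structural Cox
pp   <- sim_person_periods(sim, "renal")
spec <- weight_spec(denominator = c("egfr", "egfr_lag", "tx", "tx_lag"))
wpp  <- fit_time_varying_ipw(pp, spec)
fit  <- fit_weighted_cox(survival::Surv(start_day, end_day, event) ~ exposure,
                         data = wpp, weights = wpp$sw)
fit
#> Weighted Cox fit (breslow ties): 6000 subjects, 664 events
#>           logHR     HR robust_se lower95 upper95
#> exposure 0.7112 2.0365    0.0896  1.7086  2.4274

## the naive covariate-adjusted time-dependent Cox overshoots
coef(survival::coxph(survival::Surv(start_day, end_day, event) ~
                       exposure + egfr + egfr_lag + tx + tx_lag + age + sex,
                     data = pp))[1]
#>  exposure
#> 0.8350568
```

The weighted estimate (HR 2.04, 95% CI 1.71–2.43; truth 2.0) recovers the
causal effect. The covariate-adjusted model (log-HR 0.84 against a truth of
ln 2 ≈ 0.69) is biased by frailty-driven survivor selection, and the crude
fit (log-HR 1.65) is biased much further by the confounding itself. The full
raw-table route — cohort construction, derived outcomes, imputation,
weights, all fits and paper-shaped report tables (baseline characteristics
with standardized mean differences, incidence per 1000 patient-years with
exact Poisson intervals, hazard ratios, survival at years 1/3/6) — runs
with:

```r
run_pipeline("msm_out", sim = sim_config(n_subjects = 500, seed = 11))
```

A thin CLI over the same functions lives in
`inst/scripts/msm-anemia.R` (`simulate` and `pipeline` subcommands).

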